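test_that("osmolarity applies van't Hoff factors", {
  expect_identical(osmolarity(solute_mixture()), 0)
  expect_equal(osmolarity(iso_external()), 0.75)
  expect_equal(osmolarity(iso_internal()), 0.75)
  expect_equal(osmolarity(deflated_external()), 0.8)
  # custom factor override
  expect_equal(osmolarity(solute_mixture(cacl2 = 0.1,
                                         vant_hoff = c(cacl2 = 3))), 0.3)
  expect_error(solute_mixture(nacl = -0.1), ">= 0")
  expect_error(solute_mixture(nacl = 0.1, vant_hoff = c(nacl = 0.5)), ">= 1")
})

test_that("equilibrium volume ratio follows the ideal-osmometer rule", {
  expect_equal(equilibrium_volume_ratio(iso_internal(), iso_external()), 1)
  expect_equal(equilibrium_volume_ratio(iso_internal(), deflated_external()),
               0.9375)
  expect_error(equilibrium_volume_ratio(iso_internal(), solute_mixture()),
               "> 0")
  # ratio is 1 iff osmolarities are equal
  for (c_ext in c(0.6, 0.75, 0.9)) {
    ext <- solute_mixture(glucose = c_ext)
    ratio <- equilibrium_volume_ratio(iso_internal(), ext)
    expect_equal(ratio == 1, osmolarity(ext) == 0.75)
  }
})

test_that("fused radius conserves encapsulated volume", {
  expect_equal(fused_radius(3, 0), 3)
  expect_equal(fused_radius(2.5, 2.5), 2^(1 / 3) * 2.5)
  expect_equal(fused_radius(3, 4), 91^(1 / 3))
  r <- fused_radius(1.7, 3.2)
  expect_equal(r^3, 1.7^3 + 3.2^3, tolerance = 1e-12)
  expect_error(fused_radius(0, 0), "at least one")
})

test_that("area deficit matches closed forms and is maximal at equal radii", {
  expect_equal(area_deficit(2.5, 2.5), 1 - 2^(-1 / 3))
  expect_equal(area_deficit(3, 0), 0)
  expect_equal(area_deficit(3, 4), 1 - 91^(2 / 3) / 25)
  # fixed total volume (r1^3 + r2^3 = 16): scan radius splits
  r1 <- seq(0.05, 2.5, length.out = 491)
  r2 <- (16 - r1^3)^(1 / 3)
  d <- area_deficit(r1, r2)
  expect_lt(abs(r1[which.max(d)] - 2), 0.01) # maximum at the equal split
  expect_equal(max(d), 1 - 2^(-1 / 3), tolerance = 1e-4)
  expect_true(all(d <= 1 - 2^(-1 / 3) + 1e-12))
  expect_true(all(d >= 0))
})

test_that("fusion is rejected at or below the power threshold", {
  pair <- list(vesicle(2.5), vesicle(2.5))
  ev <- classify_fusion(pair, laser_power_mw = 100)
  expect_identical(ev$outcome, "rejected")
  expect_null(ev$post_fusion_vesicle)
  ev2 <- classify_fusion(pair, laser_power_mw = 150)
  expect_identical(ev2$outcome, "rejected")
  ev3 <- classify_fusion(pair, laser_power_mw = 151, clean_probability = 1)
  expect_identical(ev3$outcome, "clean")
})

test_that("deflated pairs always fuse disorderly; iso-osmotic follow the Bernoulli parameter", {
  pair <- list(vesicle(2.5), vesicle(2.5))
  for (s in 1:25) {
    ev <- classify_fusion(pair, 200, osmotic_ratio = 0.9375, rng_seed = s)
    expect_identical(ev$outcome, "disorderly")
  }
  expect_identical(
    classify_fusion(pair, 200, osmotic_ratio = 1,
                    clean_probability = 1, rng_seed = 1)$outcome, "clean")
  expect_identical(
    classify_fusion(pair, 200, osmotic_ratio = 1,
                    clean_probability = 0, rng_seed = 1)$outcome, "disorderly")
  expect_error(classify_fusion(pair, 200, clean_probability = 1.2), "0, 1")
})

test_that("classified events are seed-reproducible and volume-conserving", {
  pair <- list(vesicle(2.1), vesicle(3.3))
  e1 <- classify_fusion(pair, 200, osmotic_ratio = 1, rng_seed = 42)
  e2 <- classify_fusion(pair, 200, osmotic_ratio = 1, rng_seed = 42)
  expect_identical(e1$outcome, e2$outcome)
  expect_identical(e1$post_fusion_vesicle$radius_um,
                   e2$post_fusion_vesicle$radius_um)
  audit <- e1$volume_audit
  expect_equal(audit[["volume_out_um3"]], audit[["volume_in_um3"]],
               tolerance = 1e-12)
  expect_true(e1$area_deficit >= 0 && e1$area_deficit <= 1 - 2^(-1 / 3))
})

test_that("clean fraction converges to the Bernoulli parameter over many trials", {
  pair <- list(vesicle(2.5), vesicle(2.5))
  n <- 4000
  outcomes <- withr::with_seed(7L, vapply(seq_len(n), function(k) {
    classify_fusion(pair, 200, osmotic_ratio = 1,
                    clean_probability = 0.82)$outcome
  }, character(1)))
  frac <- mean(outcomes == "clean")
  se <- sqrt(0.82 * 0.18 / n)
  expect_lt(abs(frac - 0.82), 3 * se)
})

test_that("post-fusion composition mixes by ratio parts", {
  pair <- list(vesicle(2.5, composition = ternary_composition(1, 1, 0)),
               vesicle(2.5, composition = ternary_composition(1, 1, 3)))
  ev <- classify_fusion(pair, 200, osmotic_ratio = 1, clean_probability = 1,
                        rng_seed = 1)
  expect_identical(to_integer_ratio(ev$post_fusion_vesicle$composition),
                   c(2L, 2L, 3L))
})
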