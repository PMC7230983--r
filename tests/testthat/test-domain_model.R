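test_that("cap boundary length matches closed forms and the flat-disc limit", {
  r <- 5
  hemi <- membrane_domain("Ld", 2 * pi * r^2, r)
  expect_equal(hemi$alpha, pi / 2)
  expect_equal(boundary_length(hemi), 2 * pi * r)
  small <- membrane_domain("Ld", 1, 10)
  flat <- 2 * sqrt(pi * 1)
  expect_lt(abs(boundary_length(small) - flat) / flat, 0.005)
  # continuity to zero area
  tiny <- membrane_domain("Ld", 1e-10, 10)
  expect_lt(boundary_length(tiny), 1e-4)
  expect_error(membrane_domain("Ld", 0, 10), "\\(0, ")
  expect_error(membrane_domain("Ld", 3 * pi * 100, 10), "hemisphere")
})

test_that("line energy is gamma times summed boundary and additive over domains", {
  r <- 5
  doms <- list(membrane_domain("Ld", 2 * pi * r^2, r),
               membrane_domain("Ld", 10, r))
  cfg <- domain_configuration(r, doms, line_tension_pn = 1)
  expect_equal(line_energy(cfg),
               boundary_length(doms[[1]]) + boundary_length(doms[[2]]))
  cfg0 <- domain_configuration(r, doms, line_tension_pn = 0)
  expect_identical(line_energy(cfg0), 0)
  one <- domain_configuration(r, doms[1], line_tension_pn = 1)
  expect_equal(line_energy(one), 2 * pi * 5)
})

test_that("line tension ramps linearly to zero at the miscibility temperature", {
  expect_equal(line_tension_at(2, 21, 21, 45), 2)
  expect_equal(line_tension_at(2, 21, 45, 45), 0)
  expect_equal(line_tension_at(2, 21, 33, 45), 1)
  expect_equal(line_tension_at(2, 21, 60, 45), 0)    # clamped above T_c
  ts <- seq(21, 45, length.out = 30)
  expect_true(all(diff(line_tension_at(2, 21, ts, 45)) < 0))
  expect_error(line_tension_at(2, 50, 30, 45), "below")
})

test_that("pairwise merges conserve area, shorten boundaries and reject invalid cases", {
  r <- 5
  cfg <- domain_configuration(r, list(
    membrane_domain("Ld", 8, r), membrane_domain("Ld", 13, r),
    membrane_domain("Lo", 5, r)))
  out <- merge_pair(cfg, 1, 2)
  expect_length(out$config$domains, 2)
  merged <- out$config$domains[[2]]
  expect_equal(merged$area_um2, 21)
  expect_lt(out$event$post_boundary_um, out$event$pre_boundary_um)
  expect_lte(out$event$energy_change_pn_um, 0)
  expect_error(merge_pair(cfg, 1, 3), "different phases")
  expect_error(merge_pair(cfg, 1, 1), "distinct")
  big <- domain_configuration(r, list(
    membrane_domain("Ld", 1.6 * pi * r^2, r),
    membrane_domain("Ld", pi * r^2, r)))
  expect_error(merge_pair(big, 1, 2), "hemisphere")
})

test_that("boundary subadditivity holds across random cap pairs", {
  set.seed(3)
  r <- 5
  hemi <- 2 * pi * r^2
  for (k in 1:50) {
    a <- runif(2, 1e-3, hemi / 2)
    l_sep <- sum(vapply(a, function(x)
      boundary_length(membrane_domain("Ld", x, r)), numeric(1)))
    l_merged <- boundary_length(membrane_domain("Ld", sum(a), r))
    expect_lte(l_merged, l_sep + 1e-12)
  }
  # flat limit: equal small caps merge to 1/sqrt(2) of the summed boundary
  a_small <- 1e-4
  ratio <- boundary_length(membrane_domain("Ld", 2 * a_small, r)) /
    (2 * boundary_length(membrane_domain("Ld", a_small, r)))
  expect_equal(ratio, 1 / sqrt(2), tolerance = 1e-4)
})

test_that("sequential merging takes n-1 events in any order with conserved area and falling energy", {
  cfg <- generate_domain_configuration(9, 0.3, 5, seed = 21)
  total0 <- sum(vapply(cfg$domains, function(d) d$area_um2, numeric(1)))
  res <- sequential_merge(cfg)
  expect_length(res$events, 8)
  expect_length(res$config$domains, 1)
  expect_equal(res$config$domains[[1]]$area_um2, total0, tolerance = 1e-14)
  energies <- vapply(res$events, function(e) e$energy_change_pn_um,
                     numeric(1))
  expect_true(all(energies <= 1e-12))

  # order invariance on 5 random domains
  cfg5 <- generate_domain_configuration(5, 0.25, 4, seed = 8)
  total5 <- sum(vapply(cfg5$domains, function(d) d$area_um2, numeric(1)))
  orders <- list(
    "left-to-right",
    list(c(4, 5), c(1, 2), c(1, 2), c(1, 2)),
    list(c(1, 5), c(3, 4), c(1, 2), c(1, 2))
  )
  finals <- vapply(orders, function(o) {
    res_o <- sequential_merge(cfg5, order = o)
    expect_length(res_o$events, 4)
    res_o$config$domains[[1]]$area_um2
  }, numeric(1))
  expect_equal(finals, rep(total5, 3), tolerance = 1e-12)

  single <- sequential_merge(
    domain_configuration(5, list(membrane_domain("Ld", 3, 5))))
  expect_length(single$events, 0)
})

test_that("merge-event tables round the full event log", {
  res <- sequential_merge(generate_domain_configuration(4, 0.2, 5, seed = 2))
  tab <- merge_events_table(res$events)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$energy_change_pn_um <= 0))
  expect_true(all(tab$post_boundary_um < tab$pre_boundary_um))
})
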