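test_that("composition construction validates and normalises", {
  c1 <- ternary_composition(1, 1, 3)
  expect_equal(sum(c1$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(c1$fractions), c(0.2, 0.2, 0.6))
  expect_error(ternary_composition(0, 0, 0), "at least one")
  expect_error(ternary_composition(-1, 1, 1), ">= 0")
})

test_that("ratio-part mixing reproduces the 2:2:3 worked example", {
  mixed <- mix_amounts(ternary_composition(1, 1, 0), 1,
                       ternary_composition(1, 1, 3), 1)
  expect_identical(to_integer_ratio(mixed), c(2L, 2L, 3L))
  # idempotent on identical compositions, any weights
  c0 <- ternary_composition(2, 5, 3)
  m <- mix_amounts(c0, 0.3, c0, 1.7)
  expect_equal(m$fractions, c0$fractions, tolerance = 1e-12)
  # weighted parts
  m2 <- mix_amounts(ternary_composition(1, 0, 0), 2,
                    ternary_composition(0, 1, 0), 1)
  expect_identical(to_integer_ratio(m2), c(2L, 1L, 0L))
  expect_error(mix_amounts(c0, 0, c0, 1), "> 0")
})

test_that("area-weighted fraction mixing averages mole fractions", {
  m <- mix_fractions(ternary_composition(1, 1, 0), 10,
                     ternary_composition(1, 1, 3), 10)
  expect_equal(unname(m$fractions), c(0.35, 0.35, 0.30), tolerance = 1e-12)
  expect_identical(to_integer_ratio(m), c(7L, 7L, 6L))
  # continuity: vanishing second area recovers the first composition
  c1 <- ternary_composition(3, 1, 2)
  m2 <- mix_fractions(c1, 1, ternary_composition(0, 0, 1), 1e-12)
  expect_equal(m2$fractions, c1$fractions, tolerance = 1e-9)
  expect_error(mix_fractions(c1, -1, c1, 1), "> 0")
})

test_that("both mixing rules are commutative and weight-scale-invariant", {
  set.seed(11)
  for (k in 1:20) {
    a <- ternary_composition(runif(1), runif(1), runif(1))
    b <- ternary_composition(runif(1), runif(1), runif(1))
    w <- runif(2, 0.1, 3)
    ab <- mix_amounts(a, w[1], b, w[2])
    ba <- mix_amounts(b, w[2], a, w[1])
    expect_equal(ab$fractions, ba$fractions, tolerance = 1e-12)
    scaled <- mix_amounts(a, 5 * w[1], b, 5 * w[2])
    expect_equal(scaled$fractions, ab$fractions, tolerance = 1e-12)
    fab <- mix_fractions(a, w[1], b, w[2])
    fba <- mix_fractions(b, w[2], a, w[1])
    expect_equal(fab$fractions, fba$fractions, tolerance = 1e-12)
    # mass balance of the ratio-part rule
    expect_equal(ab$amounts, w[1] * a$amounts + w[2] * b$amounts,
                 tolerance = 1e-12)
  }
})

test_that("integer-ratio reduction finds smallest proportional triples", {
  expect_identical(to_integer_ratio(ternary_composition(2/7, 2/7, 3/7)),
                   c(2L, 2L, 3L))
  expect_identical(to_integer_ratio(ternary_composition(0.5, 0.5, 0)),
                   c(1L, 1L, 0L))
  expect_identical(to_integer_ratio(ternary_composition(0.35, 0.35, 0.3)),
                   c(7L, 7L, 6L))
  expect_identical(to_integer_ratio(ternary_composition(10, 10, 15)),
                   c(2L, 2L, 3L))
})

test_that("barycentric embedding round-trips and places the vertices", {
  verts <- diag(3)
  xy <- barycentric_to_cartesian(verts)
  expect_equal(xy, cbind(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2)),
               tolerance = 1e-15, ignore_attr = TRUE)
  set.seed(4)
  for (k in 1:25) {
    f <- runif(3)
    f <- f / sum(f)
    back <- cartesian_to_barycentric(barycentric_to_cartesian(f))
    expect_equal(as.numeric(back), f, tolerance = 1e-12)
  }
})

test_that("the shipped schematic diagram assigns the four study compositions", {
  dia <- read_phase_diagram()
  expect_s3_class(dia, "phase_diagram")
  expect_match(dia$provenance, "[Ss]chematic")
  expect_identical(phase_lookup(ternary_composition(1, 1, 0), dia),
                   "gel_liquid_coexistence")
  expect_identical(phase_lookup(ternary_composition(1, 1, 3), dia),
                   "uniform_liquid")
  expect_identical(phase_lookup(ternary_composition(2, 2, 3), dia),
                   "Lo_Ld_coexistence")
  expect_identical(phase_lookup(ternary_composition(1, 1, 1), dia),
                   "Lo_Ld_coexistence")
})

test_that("boundary points go to the first-listed region and gaps are flagged unassigned", {
  dia <- read_phase_diagram()
  # chol = 0.1 lies on the gel/LoLd boundary; gel is listed first
  expect_identical(phase_lookup(ternary_composition(0.45, 0.45, 0.1), dia),
                   "gel_liquid_coexistence")
  # a diagram covering only the gel band leaves high-chol points unassigned
  partial <- structure(list(
    regions = dia$regions[1], provenance = "test"), class = "phase_diagram")
  expect_identical(phase_lookup(ternary_composition(1, 1, 3), partial),
                   "unassigned")
})
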