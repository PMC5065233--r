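test_that("drift and noise amplitude match the model definitions", {
  p <- simple_unit_params()
  expect_equal(simple_drift_diffusion(0, 0, p),
               list(drift = 0.01, q = 0.01))
  expect_equal(simple_drift_diffusion(1.26, 1, p)$drift, 0)
  d <- simple_drift_diffusion(0, 1, p)
  expect_equal(d$drift, 1.26)
  expect_equal(d$q, sqrt(1.26 / 100))

  b <- bistable_unit_params()
  expect_equal(bistable_drift_diffusion(0, 0, b),
               list(drift = 0.01, q = 0.01))
  d <- bistable_drift_diffusion(1, 0, b)
  expect_equal(d$drift, 0.26)
  expect_equal(d$q, sqrt(2.26 / 100))
  # the small signal enters the drift but is neglected in the propensities
  d2 <- bistable_drift_diffusion(1, 0.005, b)
  expect_equal(d2$drift, 0.265)
  expect_equal(d2$q, d$q)

  e <- excitable_unit_params()
  d <- excitable_drift_diffusion(c(0, 0), 0, e)
  expect_equal(unname(d$drift[1, ]), c(0.004, 0.826))
  expect_equal(d$q, sqrt(1.826 / 500))
  expect_equal(unname(excitable_drift_diffusion(c(0, 0), 0.9, e)$drift[1, 2]),
               1.726)

  expect_error(simple_drift_diffusion(-1, 0, p), "non-negative")
  expect_error(bistable_drift_diffusion(-0.1, 0, b), "non-negative")
  expect_error(excitable_drift_diffusion(c(-1, 0), 0, e), "non-negative")
})

test_that("noise amplitude is positive and scales as 1/sqrt(K)", {
  for (K in c(10, 100, 1000)) {
    p <- bistable_unit_params(K = K)
    q <- bistable_drift_diffusion(c(0, 0.5, 2), 0, p)$q
    expect_true(all(q > 0))
    expect_equal(q * sqrt(K), bistable_drift_diffusion(c(0, 0.5, 2), 0,
                   bistable_unit_params(K = 1))$q, tolerance = 1e-12)
  }
})

test_that("fixed points of 1-D units match the cubic/scan oracles", {
  p <- simple_unit_params()
  fp <- deterministic_fixed_points(p = p, x = 1)
  expect_equal(nrow(fp), 1)
  expect_true(fp$stable)
  expect_equal(fp$y, 1.26, tolerance = 1e-9)

  b <- bistable_unit_params()
  fp0 <- deterministic_fixed_points(p = b, x = 0)
  expect_equal(nrow(fp0), 3)
  expect_equal(fp0$y, bistable_cubic_roots(x = 0), tolerance = 1e-8)
  expect_equal(fp0$stable, c(TRUE, FALSE, TRUE))  # stability alternates
  expect_equal(fp0$y[1], 0.0103, tolerance = 1e-2)
  expect_equal(fp0$y[3], 2.017, tolerance = 1e-3)

  # far above the saddle-node: a single (high) stable root
  fph <- deterministic_fixed_points(p = b, x = 1)
  expect_equal(nrow(fph), 1)
  expect_true(fph$stable)
})

test_that("saddle-node threshold is found by bisection and shifts with alpha0", {
  b <- bistable_unit_params()
  xsn <- bifurcation_threshold(b)
  # scan oracle: root count flips between the bracketing values
  expect_equal(nrow(deterministic_fixed_points(p = b, x = xsn - 1e-4)), 3)
  expect_equal(nrow(deterministic_fixed_points(p = b, x = xsn + 1e-4)), 1)
  # larger basal rate needs less signal to destroy the low branch
  xsn2 <- bifurcation_threshold(bistable_unit_params(alpha0 = 0.03))
  expect_lt(xsn2, xsn)
  # no feedback, no bistability
  expect_warning(out <- bifurcation_threshold(
    bistable_unit_params(alpha = 1e-3)), "not bistable")
  expect_true(is.na(out))
})

test_that("stochastic switching threshold sits near 0.001 and tracks omega", {
  b <- bistable_unit_params()
  xs <- switching_threshold(b)
  expect_gt(xs, 5e-4)
  expect_lt(xs, 2e-3)
  # equal-depth condition is independent of K
  expect_equal(switching_threshold(bistable_unit_params(K = 1000)), xs,
               tolerance = 1e-6)
  # the threshold is monotone in, and exponentially sensitive to, the
  # dissociation-scale multiplier: a few percent up moves it an order of
  # magnitude, a fraction of a percent down collapses it below zero
  x102 <- switching_threshold(bistable_unit_params(omega = 1.02))
  x105 <- switching_threshold(bistable_unit_params(omega = 1.05))
  expect_gt(x102, xs)
  expect_gt(x105, x102)
  expect_warning(lo <- switching_threshold(bistable_unit_params(omega = 0.99)),
                 "already deeper")
  expect_true(is.na(lo))
})

test_that("excitable unit has a stable low rest state separated by a saddle", {
  e <- excitable_unit_params()
  fp <- deterministic_fixed_points(p = e, x = 0)
  expect_gte(nrow(fp), 2)
  expect_true(fp$stable[1])          # rest state
  expect_lt(fp$y[1], 0.05)
  expect_gt(fp$z[1], 4)
  expect_false(fp$stable[2])         # saddle above it
})

test_that("Heaviside response implements the tie-as-crossing convention", {
  p <- heaviside_unit_params(theta = 1)
  expect_identical(heaviside_response(1, p, xi = 0), 1L)
  expect_identical(heaviside_response(0.5, p, xi = 0.6), 1L)
  expect_identical(heaviside_response(0.5, p, xi = 0), 0L)
})

test_that("unit parameters round-trip through the flat-list form", {
  for (p in list(simple_unit_params(K = 42), bistable_unit_params(omega = 1.2),
                 excitable_unit_params(), heaviside_unit_params(noise_sd = 1))) {
    expect_equal(unit_params_from_list(unit_params_to_list(p)), p)
  }
  expect_error(unit_params_from_list(list(model = "nope")), "unknown model")
  expect_error(bistable_unit_params(alpha0 = -1), "positive")
})
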