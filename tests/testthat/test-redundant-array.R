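test_that("threshold multipliers are positive, unbiased, and exact at sd 0", {
  expect_identical(draw_unit_multipliers(5, 0), rep(1, 5))
  o <- draw_unit_multipliers(10000, 0.1, seed = 1)
  expect_true(all(o > 0))
  expect_lt(abs(mean(o) - 1), 3 * sd(o) / sqrt(length(o)))
  # heavy redraw regime still yields positive values only
  o2 <- draw_unit_multipliers(2000, 2, seed = 2)
  expect_true(all(o2 > 0))
})

test_that("the summed response equals the per-unit sum exactly", {
  cfg <- array_config(N = 3, params = bistable_unit_params(),
                      heterogeneity_sd = 0.05)
  d <- run_ensemble(cfg, input_distribution("log10-uniform", 0.005), 300,
                    seed = 3)
  expect_equal(d$dy, d$dy_1 + d$dy_2 + d$dy_3, tolerance = 1e-12)
})

test_that("noiseless identical units double the single-unit response", {
  p <- bistable_unit_params(K = 1e12)
  d2 <- run_ensemble(array_config(N = 2, params = p),
                     input_distribution("log10-uniform", 0.005), 300,
                     seed = 4)
  expect_equal(d2$dy, 2 * d2$dy_1, tolerance = 1e-9)
  # deterministic: response is a function of x alone
  agg <- tapply(d2$dy, d2$x, function(v) diff(range(v)))
  expect_true(all(agg < 1e-9))
})

test_that("homogeneous uncoupled units are exchangeable", {
  cfg <- array_config(N = 2, params = bistable_unit_params())
  d <- run_ensemble(cfg, input_distribution("log10-uniform", 0.005), 2000,
                    seed = 5)
  expect_gt(suppressWarnings(ks.test(d$dy_1, d$dy_2)$p.value), 0.01)
  expect_lt(abs(mean(d$dy_1) - mean(d$dy_2)), 0.1)
})

test_that("binary outputs live on the 0..N alphabet", {
  cfg <- array_config(N = 4, params = bistable_unit_params(),
                      output = "binary")
  d <- run_ensemble(cfg, input_distribution("log10-uniform", 0.001), 500,
                    seed = 6)
  expect_true(all(d$dy %in% 0:4))
  m <- mutual_information(d$logx, d$dy)
  expect_lte(m$bits, log2(5))
})

test_that("extrinsic noise correlates the per-unit responses", {
  dist <- input_distribution("log10-uniform", 0.005)
  cors <- vapply(c(0, 0.003, 0.01), function(sd) {
    cfg <- array_config(N = 2, params = bistable_unit_params(),
                        extrinsic_sd = sd)
    d <- run_ensemble(cfg, dist, 2500, seed = 7)
    # correlation of the unit responses conditional on the signal
    r <- tapply(seq_len(nrow(d)), redinfo:::.bin_equal_width(d$logx, 8),
                function(i) if (length(i) > 30)
                  suppressWarnings(cor(d$dy_1[i], d$dy_2[i])) else NA)
    mean(unlist(r), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("ensembles are reproducible and carry a usable manifest", {
  cfg <- array_config(N = 2, params = bistable_unit_params(),
                      heterogeneity_sd = 0.1)
  dist <- input_distribution("log10-uniform", 0.005)
  d1 <- run_ensemble(cfg, dist, 150, seed = 8)
  d2 <- run_ensemble(cfg, dist, 150, seed = 8)
  expect_identical(d1, d2)
  f <- tempfile(fileext = ".csv")
  write_ensemble_csv(d1, f)
  man <- jsonlite::fromJSON(paste0(f, ".manifest.json"))
  expect_equal(man$seed, 8)
  expect_equal(man$config$N, 2)
  expect_equal(man$omegas, attr(d1, "omegas"), tolerance = 1e-9)
  expect_error(run_ensemble(cfg, dist, 150), "seed")
})

test_that("cross-talk is rejected for unsupported configurations", {
  expect_error(array_config(N = 3, params = bistable_unit_params(),
                            crosstalk = c(0.01, 0.01)), "N = 2")
  expect_error(array_config(N = 2, params = simple_unit_params(),
                            crosstalk = c(0.01, 0.01)), "bistable")
})

test_that("single-realization responses match the ensemble contract", {
  cfg <- array_config(N = 2, params = bistable_unit_params())
  r <- simulate_array_response(cfg, 0.005, seed = 9)
  expect_named(r, c("x", "logx", "dy_1", "dy_2", "dy"))
  expect_equal(r$dy, r$dy_1 + r$dy_2)
  expect_error(simulate_array_response(cfg, -1, seed = 1), "non-negative")
})

test_that("stationary and Langevin routes agree on the binary channel", {
  # at K = 100 barrier crossing is far slower than any horizon, so the
  # Langevin ensemble is initialized from the stationary density and the
  # two routes are compared on the well-occupancy (binary) readout
  p <- bistable_unit_params()
  dist <- input_distribution("log10-uniform", 0.005)
  cfg_fp <- array_config(N = 1, params = p, output = "binary")
  d_fp <- run_ensemble(cfg_fp, dist, 3000, seed = 10)
  mi_fp <- mutual_information(d_fp$logx, d_fp$dy)$bits
  set.seed(10)
  x <- sample_inputs(dist, 3000)
  cfg_sde <- array_config(N = 1, params = p, output = "binary",
                          response_source = "sde",
                          integration = integration_config(t_max = 20))
  r <- redinfo:::.responses_sde(cfg_sde, x, 1, rep(0, 3000),
                                init = "stationary")
  mi_sde <- mutual_information(log10(x), r[, 1],
                               mi_config(output_mode = "discrete"))$bits
  expect_lt(abs(mi_fp - mi_sde) / mi_fp, 0.05)
})
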