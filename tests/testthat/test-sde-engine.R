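test_that("noiseless integration endpoints match deterministic fixed points", {
  # bistable below the saddle-node: stays in the low basin
  b <- bistable_unit_params(K = 1e12)
  tr <- integrate_unit(p = b, waveform = signal_waveform("step", 0.005),
                       cfg = integration_config(seed = 1))
  lo <- deterministic_fixed_points(p = b, x = 0.005)$y[1]
  expect_equal(unname(tail(tr$states[, "y"], 1)), lo, tolerance = 1e-3)
  # above the saddle-node: switches to the single high fixed point,
  # cross-checked against an independent ODE solver
  tr2 <- integrate_unit(p = b, waveform = signal_waveform("step", 0.2),
                        cfg = integration_config(seed = 1))
  hi <- deterministic_fixed_points(p = b, x = 0.2)
  expect_equal(nrow(hi), 1)
  expect_equal(unname(tail(tr2$states[, "y"], 1)), hi$y, tolerance = 1e-3)
  expect_equal(ode_endpoint(b, 0.2, 0.0103), hi$y, tolerance = 1e-6)
  # simple unit across a grid of signals
  s <- simple_unit_params(K = 1e12)
  for (x in c(0, 0.3, 1, 3)) {
    tr3 <- integrate_unit(p = s, waveform = signal_waveform("step", x),
                          cfg = integration_config(seed = 1))
    expect_equal(unname(tail(tr3$states[, "y"], 1)),
                 deterministic_fixed_points(p = s, x = x)$y[1],
                 tolerance = 1e-3)
  }
})

test_that("zero-amplitude noiseless trajectories stay at rest; seeds reproduce", {
  b <- bistable_unit_params(K = 1e12)
  tr <- integrate_unit(p = b, waveform = signal_waveform("step", 0),
                       cfg = integration_config(t_max = 10, seed = 2))
  expect_lt(diff(range(tr$states[, "y"])), 1e-6)
  b2 <- bistable_unit_params()
  t1 <- integrate_unit(p = b2, waveform = signal_waveform("step", 0.005),
                       cfg = integration_config(t_max = 5, seed = 7))
  t2 <- integrate_unit(p = b2, waveform = signal_waveform("step", 0.005),
                       cfg = integration_config(t_max = 5, seed = 7))
  expect_identical(t1$states, t2$states)
})

test_that("halving dt leaves noiseless endpoints essentially unchanged", {
  b <- bistable_unit_params(K = 1e12)
  e1 <- tail(integrate_unit(p = b, waveform = signal_waveform("step", 0.2),
                            cfg = integration_config(dt = 0.01,
                                                     seed = 1))$states[, 1], 1)
  e2 <- tail(integrate_unit(p = b, waveform = signal_waveform("step", 0.2),
                            cfg = integration_config(dt = 0.005,
                                                     seed = 1))$states[, 1], 1)
  expect_lt(abs(e1 - e2), 1e-4)
})

test_that("response_delta recovers fixed-point differences", {
  s <- simple_unit_params(K = 1e12)
  tr <- integrate_unit(p = s, waveform = signal_waveform("step", 1),
                       cfg = integration_config(seed = 1))
  expect_equal(as.numeric(response_delta(tr)), 1.25, tolerance = 1e-3)
  tr0 <- integrate_unit(p = s, waveform = signal_waveform("step", 0),
                        cfg = integration_config(seed = 1))
  expect_equal(as.numeric(response_delta(tr0)), 0, tolerance = 1e-6)
  b <- bistable_unit_params(K = 1e12)
  trb <- integrate_unit(p = b, waveform = signal_waveform("step", 0.2),
                        cfg = integration_config(seed = 1))
  d <- response_delta(trb)
  expect_equal(as.numeric(d),
               deterministic_fixed_points(p = b, x = 0.2)$y[1] - 0.0103,
               tolerance = 5e-3)
  expect_true(attr(d, "stationary"))
})

test_that("excitation classifier separates strong and weak deterministic pulses", {
  e <- excitable_unit_params(K = 1e18)
  cfg <- integration_config(dt = 0.01, t_max = 151)
  strong <- integrate_unit(p = e, waveform = signal_waveform("pulse", 9),
                           cfg = cfg)
  weak <- integrate_unit(p = e, waveform = signal_waveform("pulse", 0.09),
                         cfg = cfg)
  none <- integrate_unit(p = e, waveform = signal_waveform("pulse", 0),
                         cfg = cfg)
  expect_identical(classify_excitation(strong, excitable_unit_params()), 1L)
  expect_identical(classify_excitation(weak, excitable_unit_params()), 0L)
  expect_identical(classify_excitation(none, excitable_unit_params()), 0L)
})

test_that("bistable binarization follows the OFF-below-one rule", {
  expect_identical(binarize_bistable(c(0.99, 1, 2.02)), c(0L, 1L, 1L))
})

test_that("trajectories export to tidy CSV", {
  b <- bistable_unit_params()
  tr <- integrate_unit(p = b, waveform = signal_waveform("step", 0.005),
                       cfg = integration_config(t_max = 2, seed = 1))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  d <- read.csv(f)
  expect_named(d, c("t", "y"))
  expect_equal(nrow(d), length(tr$times))
})

test_that("Euler-Maruyama preserves the stationary Fokker-Planck density", {
  # initialize an ensemble from the stationary density, integrate for 20
  # time units at K = 100, and compare the final states to the density
  b <- bistable_unit_params()
  x <- 0.005
  dens <- stationary_density_fp(p = b, x = x)
  set.seed(11)
  R <- 1500
  y0 <- matrix(sample(dens$y, R, replace = TRUE, prob = dens$density), R, 1)
  sim <- redinfo:::.em_ensemble_1d(1L, rep(x, R), rep(0, R), 1, c(0, 0),
                                   b$alpha0, b$alpha, b$n, b$K, 0.01, 2000L,
                                   0.2, y0)
  expect_lt(ks_to_density(sim$last[, 1], dens), 0.05)
})

test_that("downstream MI is insensitive to halving dt where mixing is fast", {
  # at K = 20 the barrier is low enough for the Langevin route to
  # equilibrate within the horizon
  p <- bistable_unit_params(K = 20)
  dist <- input_distribution("log10-uniform", 0.005)
  mi_at <- function(dt, seed) {
    cfg <- array_config(N = 1, params = p, response_source = "sde",
                        integration = integration_config(dt = dt, t_max = 50))
    d <- run_ensemble(cfg, dist, 3000, seed = seed)
    mutual_information(d$logx, d$dy)$bits
  }
  m1 <- mean(sapply(5:7, mi_at, dt = 0.01))
  m2 <- mean(sapply(5:7, mi_at, dt = 0.005))
  expect_lt(abs(m1 - m2) / m1, 0.05)
})
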