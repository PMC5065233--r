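test_that("interior-maximum detection requires a genuinely interior peak", {
  mk <- function(means) {
    do.call(rbind, lapply(seq_along(means), function(i)
      data.frame(v = i, replicate = 1:6, mi = means[i] + seq(-0.01, 0.01,
                                                             length.out = 6))))
  }
  peaked <- redinfo:::.new_scan(mk(c(0.2, 0.5, 0.9, 0.5, 0.2)), "v", NULL)
  flat <- redinfo:::.new_scan(mk(c(0.2, 0.202, 0.2, 0.202, 0.2)), "v", NULL)
  edge <- redinfo:::.new_scan(mk(c(0.9, 0.5, 0.3, 0.2, 0.1)), "v", NULL)
  expect_true(has_interior_maximum(peaked))
  expect_equal(attr(has_interior_maximum(peaked), "peak"), 3)
  expect_false(has_interior_maximum(flat))
  expect_false(has_interior_maximum(edge))
})

test_that("scan drivers emit tidy replicated tables and are reproducible", {
  s1 <- noise_resonance_scan(dist_mean = 0.01, N = 1, K_grid = c(100, 1e12),
                             n_real = 300, replicates = 2, seed = 42)
  s2 <- noise_resonance_scan(dist_mean = 0.01, N = 1, K_grid = c(100, 1e12),
                             n_real = 300, replicates = 2, seed = 42)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_named(as.data.frame(s1), c("K", "noise_amplitude", "replicate", "mi"))
  expect_equal(nrow(s1), 4)
  expect_true(all(s1$mi >= 0))
  sm <- summarize_scan(s1, "mi", "K")
  expect_named(sm, c("K", "mean", "se", "n"))
})

test_that("redundancy scans report the reference MI alongside ratios", {
  s <- redundancy_scan("bistable", N_grid = c(1, 3), n_real = 400,
                       replicates = 2, seed = 11)
  expect_true(all(c("mi", "mi_ref", "relative_mi") %in% names(s)))
  expect_equal(s$relative_mi[s$N == 1], rep(1, 2))
  expect_equal(s$mi, s$relative_mi * s$mi_ref)
})

test_that("suprathreshold Heaviside array: one bit at zero noise for N = 1", {
  s <- suprathreshold_sr_scan(N_grid = 1, sigma_grid = c(0, 0.5),
                              n_real = 8000, replicates = 2, seed = 12)
  m0 <- mean(s$mi[s$sigma == 0])
  expect_equal(m0, 1, tolerance = 0.05)
  # balanced deterministic channel: output entropy is the full bit
  expect_gt(m0, 0.95)
  expect_lt(mean(s$mi[s$sigma == 0.5]), m0)
})

test_that("genetic-load arithmetic follows the growth-cost formula exactly", {
  mi_tab <- data.frame(N = 1:10, mi = seq(0.4, 1.3, length.out = 10))
  g <- genetic_load_tradeoff(N_grid = 1:10, S = 100, mi_by_N = mi_tab)
  expect_equal(g$growth, 1 - 100 * (1:10 - 1) / (5000 * 0.48))
  expect_equal(g$growth[g$N == 1], 1)
  expect_equal(g$phi[g$N == 10], 0.18)
  expect_equal(g$growth[g$N == 10], 0.625)
  g1 <- genetic_load_tradeoff(N_grid = 1:10, S = 1, mi_by_N = mi_tab)
  expect_true(all(g1$growth > 0.995))   # negligible load for a single system
  # clamping kicks in when the load exceeds the viability limit
  expect_warning(gX <- genetic_load_tradeoff(N_grid = c(1, 30), S = 100,
    mi_by_N = data.frame(N = c(1, 30), mi = c(0.4, 1.5))), "clamped")
  expect_equal(gX$growth[gX$N == 30], 0)
  # Pareto front: monotone mi means every point is non-dominated
  expect_true(all(g$pareto))
})

test_that("experiment configs run end to end through the CLI runner", {
  out <- tempfile()
  cfgf <- tempfile(fileext = ".yaml")
  writeLines(c("experiment: noise_resonance",
               "seed: 7",
               "args:",
               "  dist_mean: 0.001",
               "  \"N\": 1",
               "  K_grid: [1.0e+12]",
               "  n_real: 2000",
               "  replicates: 1"), cfgf)
  res <- run_experiment_file(cfgf, output_dir = out)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "log.txt")))
  # noiseless unit at a threshold-centered input carries ~1 bit
  r <- read.csv(file.path(out, "results.csv"))
  expect_equal(r$mi, 1, tolerance = 0.02)
  # byte-identical rerun
  out2 <- tempfile()
  run_experiment_file(cfgf, output_dir = out2)
  expect_identical(readLines(file.path(out, "results.csv")),
                   readLines(file.path(out2, "results.csv")))
})

test_that("the CLI runner validates its schema with field-level messages", {
  expect_error(run_experiment_file(list(experiment = "noise_resonance")),
               "`seed`")
  expect_error(run_experiment_file(list(experiment = "nope", seed = 1)),
               "unknown experiment")
  expect_error(run_experiment_file(list(experiment = "redundancy", seed = 1,
                                        args = list(bogus_field = 2))),
               "bogus_field")
})

test_that("the experiment catalog is stable and JSON round-trippable", {
  cat0 <- list_experiments()
  expect_true(all(c("noise_resonance", "heterogeneity", "crosstalk",
                    "suprathreshold_sr", "genetic_load") %in% cat0$name))
  j <- jsonlite::fromJSON(jsonlite::toJSON(cat0))
  expect_equal(j$name, cat0$name)
})
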