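# Scan drivers regenerating each figure-class analysis as a tidy table.
# Every driver derives one sub-seed per (grid point, replicate) from the
# top-level seed, so results are reproducible bit for bit.

.sub_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.new_scan <- function(df, scan_var, config) {
  structure(df, scan_var = scan_var, config = config,
            class = c("scan_result", "data.frame"))
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> over `%s` (%d rows)\n",
              attr(x, "scan_var"), nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Summarize a scan over replicates
#'
#' Mean and standard error of a value column per scan point (and optional
#' grouping columns).
#'
#' @param scan a `scan_result`.
#' @param value column to aggregate (default `"mi"`).
#' @param by grouping columns (defaults to the scan variable).
#' @return data frame with columns `by`, `mean`, `se`, `n`.
#' @export
summarize_scan <- function(scan, value = "mi", by = attr(scan, "scan_var")) {
  sp <- split(scan[[value]], scan[by], drop = TRUE)
  keys <- unique(scan[by])
  keys <- keys[order(do.call(order, keys)), , drop = FALSE]
  agg <- do.call(rbind, lapply(sp, function(v)
    data.frame(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
               n = length(v))))
  ord <- do.call(order, scan[!duplicated(scan[by]), by, drop = FALSE])
  out <- cbind(unique(scan[by]), agg[names(sp), ])
  rownames(out) <- NULL
  out[order(out[[by[1]]]), , drop = FALSE]
}

#' Detect an interior maximum in a replicated scan
#'
#' A scan has an interior maximum when the largest replicate-averaged value
#' occurs strictly inside the grid and exceeds both grid-end averages by
#' more than `z` combined standard errors.
#'
#' @param scan a `scan_result` (or summary data frame with `mean`/`se`).
#' @param value value column.
#' @param by scan variable.
#' @param z separation requirement in combined SE units (default 2).
#' @return logical; attribute `peak` holds the peak scan value.
#' @export
has_interior_maximum <- function(scan, value = "mi",
                                 by = attr(scan, "scan_var"), z = 2) {
  s <- if (all(c("mean", "se") %in% names(scan))) scan
       else summarize_scan(scan, value, by)
  k <- which.max(s$mean)
  ok <- k > 1 && k < nrow(s)
  if (ok) {
    for (e in c(1L, nrow(s))) {
      gap <- s$mean[k] - s$mean[e]
      comb <- sqrt(s$se[k]^2 + s$se[e]^2)
      if (!(gap > z * comb)) ok <- FALSE
    }
  }
  structure(ok, peak = s[[by]][k])
}

# shared inner loop: MI of one ensemble
.ensemble_mi <- function(cfg, dist, n_real, seed, mi_cfg = NULL) {
  if (is.null(mi_cfg))
    mi_cfg <- mi_config(output_mode = if (cfg$output == "binary" ||
                                          cfg$params$kind == "excitable")
                        "discrete" else "continuous")
  d <- run_ensemble(cfg, dist, n_real, seed)
  mutual_information(d$logx, d$dy, mi_cfg)$bits
}

#' Mutual information versus intrinsic noise (stochastic-resonance scan)
#'
#' Scans MI of a bistable array with binary readout against intrinsic noise
#' strength (parameterized by the molecule-number scale `K`; amplitude
#' `1/sqrt(K)`). With the input centered above the switching threshold a
#' single unit shows an interior maximum (stochastic resonance); centered
#' at the threshold, noise only degrades a single unit but an interior
#' maximum reappears for `N >= 2` (suprathreshold stochastic resonance).
#'
#' @param dist_mean center of the log10-uniform input (default: the
#'   bistable switching threshold).
#' @param N number of units.
#' @param K_grid molecule-number grid (use large values, e.g. `1e12`, for
#'   the noiseless limit).
#' @param n_real realizations per MI estimate.
#' @param replicates replicate MI estimates per grid point.
#' @param seed top-level seed.
#' @param params bistable unit parameters.
#' @return a `scan_result` with columns `K`, `noise_amplitude`, `replicate`,
#'   `mi`.
#' @export
noise_resonance_scan <- function(dist_mean = NULL, N = 1,
                                 K_grid = c(10, 30, 100, 300, 1000, 3000,
                                            1e4, 1e12),
                                 n_real = 1000, replicates = 5, seed = 1,
                                 params = bistable_unit_params()) {
  if (is.null(dist_mean)) dist_mean <- switching_threshold(params)
  dist <- input_distribution("log10-uniform", dist_mean)
  seeds <- .sub_seeds(seed, replicates)   # shared across the grid: paired
  rows <- list()
  for (i in seq_along(K_grid)) {
    p <- params; p$K <- K_grid[i]
    cfg <- array_config(N = N, params = p, output = "binary")
    for (r in seq_len(replicates))
      rows[[length(rows) + 1]] <- data.frame(
        K = K_grid[i], noise_amplitude = 1 / sqrt(K_grid[i]), replicate = r,
        mi = .ensemble_mi(cfg, dist, n_real, seeds[r]))
  }
  .new_scan(do.call(rbind, rows), "K",
            list(dist_mean = dist_mean, N = N, n_real = n_real, seed = seed))
}

# default input distribution centered on a unit's threshold
.threshold_dist <- function(kind) {
  mean <- switch(kind, simple = 1, bistable = 0.001, excitable = 0.9)
  input_distribution("log10-uniform", mean)
}

#' Relative mutual information versus number of redundant units
#'
#' MI of the summed response for `N` in `N_grid`, relative to `N = 1`, with
#' the input centered on the unit's threshold (1 for the simple unit, 0.001
#' for the bistable unit, 0.9 for the excitable unit). With `noiseless =
#' TRUE` the units are deterministic and relative MI stays at 1 for all
#' `N`.
#'
#' @param kind `"simple"`, `"bistable"` or `"excitable"`.
#' @param N_grid unit counts (must include 1, the reference).
#' @param dist input distribution (default: threshold-centered uniform).
#' @param noiseless run the deterministic control instead of noisy units.
#' @inheritParams noise_resonance_scan
#' @return a `scan_result` with columns `N`, `replicate`, `mi`, `mi_ref`,
#'   `relative_mi`.
#' @export
redundancy_scan <- function(kind = "bistable", N_grid = 1:5, dist = NULL,
                            n_real = 1000, replicates = 5, seed = 1,
                            noiseless = FALSE, params = NULL) {
  if (is.null(params))
    params <- switch(kind, simple = simple_unit_params(),
                     bistable = bistable_unit_params(),
                     excitable = excitable_unit_params())
  if (noiseless && kind != "excitable") params$K <- 1e12
  if (noiseless && kind == "excitable") params$K <- 1e18
  if (is.null(dist)) dist <- .threshold_dist(kind)
  if (!1 %in% N_grid) N_grid <- c(1, N_grid)
  N_grid <- sort(unique(N_grid))
  seeds <- .sub_seeds(seed, replicates)   # shared across N: paired ratios
  rows <- list()
  ref <- numeric(replicates)
  for (i in seq_along(N_grid)) {
    cfg <- array_config(N = N_grid[i], params = params)
    for (r in seq_len(replicates)) {
      mi <- .ensemble_mi(cfg, dist, n_real, seeds[r])
      if (N_grid[i] == 1) ref[r] <- mi
      rows[[length(rows) + 1]] <- data.frame(
        N = N_grid[i], replicate = r, mi = mi, mi_ref = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  out$mi_ref <- ref[out$replicate]
  out$relative_mi <- out$mi / out$mi_ref
  .new_scan(out, "N", list(kind = kind, noiseless = noiseless,
                           n_real = n_real, seed = seed,
                           dist = unclass(dist)))
}

#' Effect of the input distribution on the redundancy gain
#'
#' Relative MI (vs `N = 1`) of bistable arrays for the three input families
#' at the threshold-centered mean, and for the log10-uniform family at a
#' set of means around the threshold.
#'
#' @param families input families to compare at `mean = means[1]`.
#' @param means input means for the uniform family (first value should be
#'   the threshold).
#' @param N_grid unit counts.
#' @inheritParams noise_resonance_scan
#' @return a `scan_result` with columns `family`, `mean`, `N`, `replicate`,
#'   `mi`, `relative_mi`.
#' @export
input_distribution_scan <- function(families = c("log10-uniform", "lognormal",
                                                 "log-beta"),
                                    means = c(0.001, 0.005, 0.01),
                                    N_grid = c(1, 5), n_real = 1000,
                                    replicates = 5, seed = 1,
                                    params = bistable_unit_params()) {
  combos <- rbind(
    data.frame(family = families, mean = means[1]),
    data.frame(family = "log10-uniform", mean = means[-1]))
  combos <- unique(combos)
  if (!1 %in% N_grid) N_grid <- c(1, N_grid)
  N_grid <- sort(unique(N_grid))
  seeds <- matrix(.sub_seeds(seed, nrow(combos) * replicates), nrow(combos))
  rows <- list()
  for (c0 in seq_len(nrow(combos))) {
    dist <- input_distribution(combos$family[c0], combos$mean[c0])
    ref <- numeric(replicates)
    for (i in seq_along(N_grid)) {
      cfg <- array_config(N = N_grid[i], params = params)
      for (r in seq_len(replicates)) {
        mi <- .ensemble_mi(cfg, dist, n_real, seeds[c0, r])
        if (N_grid[i] == 1) ref[r] <- mi
        rows[[length(rows) + 1]] <- data.frame(
          family = combos$family[c0], dist_mean = combos$mean[c0],
          N = N_grid[i], replicate = r, mi = mi,
          relative_mi = mi / ref[r])
      }
    }
  }
  .new_scan(do.call(rbind, rows), "N",
            list(n_real = n_real, seed = seed))
}

#' Mutual information versus extrinsic-noise strength
#'
#' MI of bistable arrays under a shared extrinsic production offset of
#' increasing standard deviation (input centered at 0.005), for `N = 5` and
#' the `N = 1` reference. Relative MI is with respect to zero extrinsic
#' noise at the same `N`.
#'
#' @param extrinsic_grid standard deviations of the shared offset.
#' @param N_values array sizes to compare.
#' @param dist_mean input center.
#' @inheritParams noise_resonance_scan
#' @return a `scan_result` with columns `extrinsic_sd`, `N`, `replicate`,
#'   `mi`, `relative_mi`.
#' @export
extrinsic_noise_scan <- function(extrinsic_grid = c(0, 0.001, 0.002, 0.005,
                                                    0.01),
                                 N_values = c(1, 5), dist_mean = 0.005,
                                 n_real = 1000, replicates = 5, seed = 1,
                                 params = bistable_unit_params()) {
  dist <- input_distribution("log10-uniform", dist_mean)
  seeds <- matrix(.sub_seeds(seed, length(N_values) * replicates),
                  length(N_values))
  rows <- list()
  for (j in seq_along(N_values)) {
    ref <- numeric(replicates)
    for (i in seq_along(extrinsic_grid)) {
      cfg <- array_config(N = N_values[j], params = params,
                          extrinsic_sd = extrinsic_grid[i])
      for (r in seq_len(replicates)) {
        mi <- .ensemble_mi(cfg, dist, n_real, seeds[j, r])
        if (i == 1) ref[r] <- mi
        rows[[length(rows) + 1]] <- data.frame(
          extrinsic_sd = extrinsic_grid[i], N = N_values[j], replicate = r,
          mi = mi, relative_mi = mi / ref[r])
      }
    }
  }
  .new_scan(do.call(rbind, rows), "extrinsic_sd",
            list(dist_mean = dist_mean, n_real = n_real, seed = seed))
}

#' Mutual information versus cross-talk strength
#'
#' MI of a bistable pair whose units share Hill-site occupancy
#' (`y1 + eps2*y2`, `y2 + eps1*y1`) for increasing average cross-talk
#' `eps = (eps1 + eps2)/2`, under three asymmetry modes with the same
#' average: symmetric (`eps1 = eps2`), mixed (`1.5 eps, 0.5 eps`) and
#' one-sided (`2 eps, 0`). Relative MI is with respect to `eps = 0` within
#' each mode.
#'
#' @param eps_grid average cross-talk strengths.
#' @param modes asymmetry modes to include.
#' @inheritParams extrinsic_noise_scan
#' @return a `scan_result` with columns `eps`, `mode`, `replicate`, `mi`,
#'   `relative_mi`.
#' @export
crosstalk_scan <- function(eps_grid = c(0, 1e-4, 3e-4, 1e-3, 3e-3, 0.01),
                           modes = c("symmetric", "mixed", "onesided"),
                           dist_mean = 0.005, n_real = 1000, replicates = 5,
                           seed = 1, params = bistable_unit_params()) {
  split_eps <- function(mode, e) switch(mode,
    symmetric = c(e, e), mixed = c(1.5 * e, 0.5 * e), onesided = c(2 * e, 0))
  dist <- input_distribution("log10-uniform", dist_mean)
  seeds <- matrix(.sub_seeds(seed, length(modes) * replicates),
                  length(modes))
  rows <- list()
  for (j in seq_along(modes)) {
    ref <- numeric(replicates)
    for (i in seq_along(eps_grid)) {
      cfg <- array_config(N = 2, params = params,
                          crosstalk = split_eps(modes[j], eps_grid[i]))
      for (r in seq_len(replicates)) {
        mi <- .ensemble_mi(cfg, dist, n_real, seeds[j, r])
        if (i == 1) ref[r] <- mi
        rows[[length(rows) + 1]] <- data.frame(
          eps = eps_grid[i], mode = modes[j], replicate = r, mi = mi,
          relative_mi = mi / ref[r])
      }
    }
  }
  .new_scan(do.call(rbind, rows), "eps",
            list(dist_mean = dist_mean, n_real = n_real, seed = seed))
}

#' Mutual information versus threshold heterogeneity
#'
#' MI of a five-unit bistable array whose units carry Gaussian
#' dissociation-scale multipliers of increasing standard deviation (the
#' degree of heterogeneity), at a sharp-threshold intrinsic-noise level
#' (`K_main = 1000` by default; the gain requires units whose response
#' transition is narrow relative to the input span). The inset analysis reports the peak differential MI (peak
#' over the heterogeneity grid minus the near-zero-heterogeneity baseline)
#' for a grid of intrinsic-noise levels, showing that stronger intrinsic
#' noise erodes the benefit of heterogeneity.
#'
#' @param het_grid heterogeneity standard deviations (the near-zero
#'   baseline `1e-4` stands for "no heterogeneity" on a log axis).
#' @param N array size.
#' @param K_main molecule-number scale of the main scan.
#' @param K_grid molecule-number grid for the peak-differential analysis
#'   (`NULL` to skip).
#' @inheritParams extrinsic_noise_scan
#' @return a `scan_result` with columns `K`, `het_sd`, `replicate`, `mi`;
#'   attribute `differential` holds the per-`K` peak differential MI.
#' @export
heterogeneity_scan <- function(het_grid = c(1e-4, 0.003, 0.01, 0.03, 0.1,
                                            0.3, 1),
                               N = 5, K_main = 1000,
                               K_grid = c(100, 4000),
                               dist_mean = 0.005, n_real = 1000,
                               replicates = 5, seed = 1,
                               params = bistable_unit_params()) {
  Ks <- unique(c(K_main, K_grid))
  seeds <- matrix(.sub_seeds(seed, length(Ks) * replicates), length(Ks))
  rows <- list()
  for (k in seq_along(Ks)) {
    p <- params; p$K <- Ks[k]
    for (i in seq_along(het_grid)) {
      cfg <- array_config(N = N, params = p, heterogeneity_sd = het_grid[i])
      for (r in seq_len(replicates))
        rows[[length(rows) + 1]] <- data.frame(
          K = Ks[k], het_sd = het_grid[i], replicate = r,
          mi = .ensemble_mi(cfg, dist = input_distribution("log10-uniform",
                                                           dist_mean),
                            n_real, seeds[k, r]))
    }
  }
  out <- do.call(rbind, rows)
  diff_tab <- do.call(rbind, lapply(Ks, function(K) {
    s <- summarize_scan(.new_scan(out[out$K == K, ], "het_sd", NULL),
                        "mi", "het_sd")
    data.frame(K = K, noise_amplitude = 1 / sqrt(K),
               peak_differential = max(s$mean) - s$mean[1],
               peak_het = s$het_sd[which.max(s$mean)])
  }))
  res <- .new_scan(out, "het_sd",
                   list(K_main = K_main, dist_mean = dist_mean,
                        n_real = n_real, seed = seed))
  attr(res, "differential") <- diff_tab
  res
}

#' Suprathreshold stochastic resonance in a Heaviside array
#'
#' `N` ideal threshold units with threshold equal to the mean of a Gaussian
#' signal (`mean 1, sd 1`), each perturbed by independent Gaussian noise of
#' standard deviation `sigma`; the output is the sum of the unit responses.
#' The signal is strongly suprathreshold, yet MI versus `sigma` has an
#' interior maximum for every `N > 1` (and is maximal at zero noise for
#' `N = 1`, where it equals 1 bit). The scan also records the input-output
#' correlation coefficient, which, unlike MI, barely distinguishes noise
#' levels.
#'
#' @param N_grid array sizes.
#' @param sigma_grid unit-noise standard deviations.
#' @param signal_mean,signal_sd Gaussian signal parameters; the threshold
#'   equals `signal_mean`.
#' @inheritParams noise_resonance_scan
#' @return a `scan_result` with columns `N`, `sigma`, `replicate`, `mi`,
#'   `correlation`.
#' @export
suprathreshold_sr_scan <- function(N_grid = c(1, 2, 3, 5),
                                   sigma_grid = c(0, 0.25, 0.5, 0.75, 1,
                                                  1.5, 2, 3),
                                   signal_mean = 1, signal_sd = 1,
                                   n_real = 10000, replicates = 5, seed = 1) {
  seeds <- matrix(.sub_seeds(seed, length(N_grid) * replicates),
                  length(N_grid))
  p <- heaviside_unit_params(theta = signal_mean)
  micfg <- mi_config(n_bins_input = 100, output_mode = "discrete",
                     input_binning = "quantile")
  rows <- list()
  for (i in seq_along(N_grid)) for (j in seq_along(sigma_grid))
    for (r in seq_len(replicates)) {
      set.seed(seeds[i, r] + j)
      x <- stats::rnorm(n_real, signal_mean, signal_sd)
      y <- 0
      for (u in seq_len(N_grid[i]))
        y <- y + heaviside_response(x, p,
                                    xi = if (sigma_grid[j] > 0)
                                      stats::rnorm(n_real, 0, sigma_grid[j])
                                    else 0)
      mi <- mutual_information(x, y, micfg)$bits
      rows[[length(rows) + 1]] <- data.frame(
        N = N_grid[i], sigma = sigma_grid[j], replicate = r, mi = mi,
        correlation = suppressWarnings(stats::cor(x, y)))
    }
  .new_scan(do.call(rbind, rows), "sigma",
            list(signal_mean = signal_mean, signal_sd = signal_sd,
                 n_real = n_real, seed = seed))
}

#' Information-versus-genetic-load tradeoff of redundancy
#'
#' For a bacterium of `genome_size` genes in which `S` independent systems
#' are implemented with `N`-fold redundancy, the unnecessary-protein
#' fraction is `phi = S (N - 1) / genome_size` and the relative growth rate
#' is `1 - phi / 0.48`. Pairs the growth cost with the redundancy MI gain
#' and extracts the Pareto front.
#'
#' @param N_grid redundancy levels.
#' @param S number of redundant systems.
#' @param mi_by_N optional data frame with columns `N` and `mi` (e.g. a
#'   summarized [redundancy_scan()]); when `NULL` a bistable redundancy
#'   scan is run.
#' @param genome_size number of genes.
#' @inheritParams noise_resonance_scan
#' @return data frame with columns `N`, `S`, `phi`, `growth`,
#'   `growth_clamped`, `mi`, `relative_mi`, `pareto`.
#' @export
genetic_load_tradeoff <- function(N_grid = 1:10, S = 100, mi_by_N = NULL,
                                  genome_size = 5000, n_real = 1000,
                                  replicates = 3, seed = 1) {
  if (S < 1 || any(N_grid < 1)) stop("need S >= 1 and N >= 1")
  if (is.null(mi_by_N)) {
    sc <- redundancy_scan("bistable", N_grid = N_grid, n_real = n_real,
                          replicates = replicates, seed = seed)
    s <- summarize_scan(sc, "mi", "N")
    mi_by_N <- data.frame(N = s$N, mi = s$mean)
  }
  phi <- S * (N_grid - 1) / genome_size
  growth <- 1 - phi / 0.48
  clamped <- growth < 0
  growth_c <- pmax(growth, 0)
  mi <- mi_by_N$mi[match(N_grid, mi_by_N$N)]
  rel <- mi / mi[N_grid == 1][1]
  # Pareto front: not dominated in (mi, growth)
  pareto <- vapply(seq_along(N_grid), function(i)
    !any(mi > mi[i] & growth_c > growth_c[i] |
           (mi >= mi[i] & growth_c > growth_c[i]) |
           (mi > mi[i] & growth_c >= growth_c[i])), logical(1))
  out <- data.frame(N = N_grid, S = S, phi = phi, growth = growth_c,
                    growth_clamped = clamped, mi = mi, relative_mi = rel,
                    pareto = pareto)
  if (any(clamped))
    warning("growth rate clamped to 0 for N = ",
            paste(N_grid[clamped], collapse = ", "))
  .new_scan(out, "N", list(S = S, genome_size = genome_size, seed = seed))
}
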