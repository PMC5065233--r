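#' Configuration of a redundant array of threshold units
#'
#' An array of `N` identical-in-design units reading a common signal, with
#' three optional perturbation layers:
#'
#' * extrinsic noise: one shared Gaussian offset `xi_ex ~ N(0, extrinsic_sd)`
#'   per realization, added as a constant production-rate term to every unit
#'   for the whole response window (short-lived-protein regime);
#' * cross-talk (bistable pairs only): unit 1's autoactivation Hill argument
#'   becomes `y1 + eps2*y2` and unit 2's `y2 + eps1*y1`;
#' * heterogeneity: per-unit Gaussian multipliers `omega_i` of mean 1
#'   (sd = `heterogeneity_sd`, redrawn until positive) scaling each unit's
#'   dissociation scale, which shifts its activation threshold.
#'
#' @param N number of units (>= 1).
#' @param params a `unit_params` object shared by all units.
#' @param extrinsic_sd sd of the shared extrinsic production offset.
#' @param crosstalk length-2 numeric `c(eps1, eps2)`; non-zero values
#'   require `N = 2` bistable units.
#' @param heterogeneity_sd sd of the threshold multipliers `omega`.
#' @param output `"continuous"` for `Delta y` readouts, `"binary"` for the
#'   OFF/ON readout (`y < 1` vs `y >= 1`) used in the binary-channel
#'   analyses. The excitable unit always reports the Boolean excitation
#'   flag.
#' @param response_source `"stationary"` draws steady-state responses from
#'   the stationary Fokker-Planck density (exact at any noise level);
#'   `"sde"` integrates the chemical-Langevin equations for a finite
#'   horizon. The excitable unit always uses the Langevin route.
#' @param integration an [integration_config()] for the `"sde"` route.
#' @return an `array_config` object.
#' @examples
#' cfg <- array_config(N = 2, params = bistable_unit_params())
#' @export
array_config <- function(N = 1, params = bistable_unit_params(),
                         extrinsic_sd = 0, crosstalk = c(0, 0),
                         heterogeneity_sd = 0,
                         output = c("continuous", "binary"),
                         response_source = c("stationary", "sde"),
                         integration = NULL) {
  output <- match.arg(output)
  response_source <- match.arg(response_source)
  if (N < 1 || N != round(N)) stop("`N` must be a positive integer")
  if (extrinsic_sd < 0 || heterogeneity_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (length(crosstalk) == 1) crosstalk <- rep(crosstalk, 2)
  if (any(crosstalk < 0)) stop("cross-talk strengths must be >= 0")
  if (any(crosstalk > 0) && !(params$kind == "bistable" && N == 2))
    stop("cross-talk is only supported for N = 2 bistable units")
  if (params$kind == "excitable") response_source <- "sde"
  if (is.null(integration)) {
    integration <- if (params$kind == "excitable")
      integration_config(dt = 0.01, t_max = 151) else integration_config()
  }
  structure(list(N = as.integer(N), params = params,
                 extrinsic_sd = extrinsic_sd, crosstalk = crosstalk,
                 heterogeneity_sd = heterogeneity_sd, output = output,
                 response_source = response_source,
                 integration = integration),
            class = "array_config")
}

#' @export
print.array_config <- function(x, ...) {
  cat(sprintf(
    "<array_config> N=%d %s units, extrinsic_sd=%g, crosstalk=(%g,%g), het_sd=%g, %s output, %s responses\n",
    x$N, x$params$kind, x$extrinsic_sd, x$crosstalk[1], x$crosstalk[2],
    x$heterogeneity_sd, x$output, x$response_source))
  invisible(x)
}

#' Per-unit threshold multipliers
#'
#' Draws `N` i.i.d. Gaussian multipliers of mean 1 and the given standard
#' deviation, redrawing any non-positive value (rather than clipping, which
#' would bias the mean). `sd = 0` returns exact ones.
#'
#' @param N number of units.
#' @param heterogeneity_sd standard deviation of the multipliers.
#' @param seed optional integer seed.
#' @return numeric vector of `N` positive multipliers.
#' @export
draw_unit_multipliers <- function(N, heterogeneity_sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (heterogeneity_sd < 0) stop("`heterogeneity_sd` must be >= 0")
  if (heterogeneity_sd == 0) return(rep(1, N))
  o <- stats::rnorm(N, 1, heterogeneity_sd)
  while (any(o <= 0))
    o[o <= 0] <- stats::rnorm(sum(o <= 0), 1, heterogeneity_sd)
  o
}

# baseline rest expression of unit i (given its omega multiplier)
.unit_baseline <- function(params, omega) {
  p <- params; p$omega <- omega * params$omega
  if (p$kind == "excitable") return(0)        # Boolean output, no baseline
  .rest_state(p)[1]
}

# --- response engines -------------------------------------------------------
# All engines take the realized signal vector x (length R) and the array
# configuration, and return an R x N matrix of per-unit responses
# Delta y_i (0/1 in binary mode).

.responses_stationary <- function(cfg, x, omegas, xi_ex) {
  p <- cfg$params; R <- length(x); N <- cfg$N
  out <- matrix(0, R, N)
  if (any(cfg$crosstalk > 0)) {
    # stationary cross-talk channel on a log-spaced signal grid
    xg <- exp(seq(log(min(x)), log(max(x)), length.out = 96))
    ch <- .crosstalk_channel(p, cfg$crosstalk[1], cfg$crosstalk[2], xg)
    yy <- .crosstalk_sample(ch, x)
    base <- .unit_baseline(p, 1)
    out[, 1] <- yy[, 1] - base
    out[, 2] <- yy[, 2] - base
  } else if (p$kind == "bistable") {
    xeff <- x + xi_ex
    for (j in seq_len(N)) {
      pj <- p; pj$omega <- p$omega * omegas[j]
      tb <- .fp_tables(pj)
      yj <- .fp_sample_linear(xeff, pj$K, tb$grid, tb$A0, tb$B0, tb$logq2K,
                              stats::runif(R))
      out[, j] <- yj - .unit_baseline(p, omegas[j])
    }
  } else if (p$kind == "simple") {
    grid <- seq(0, p$alpha0 + p$alpha + 1, length.out = 1601)
    for (j in seq_len(N)) {
      cc <- pmax(p$alpha0 + p$alpha *
                   .hill(x / (p$omega * omegas[j]), p$n) + xi_ex, 1e-9)
      yj <- .fp_sample_simple(cc, p$K, grid, stats::runif(R))
      out[, j] <- yj - .unit_baseline(p, omegas[j])
    }
  } else stop("stationary responses are available for 1-D units only")
  if (cfg$output == "binary") {
    base <- vapply(seq_len(N), function(j) .unit_baseline(p, omegas[j]),
                   numeric(1))
    out <- vapply(seq_len(N), function(j)
      as.numeric(binarize_bistable(out[, j] + base[j])), numeric(R))
    if (R == 1) out <- matrix(out, 1, N)
  }
  out
}

.responses_sde <- function(cfg, x, omegas, xi_ex, init = "baseline") {
  p <- cfg$params; R <- length(x); N <- cfg$N
  ic <- cfg$integration
  nsteps <- round(ic$t_max / ic$dt)
  if (p$kind == "excitable") {
    thr <- excitation_threshold(p)
    rest <- .rest_state(p)
    pulse_steps <- as.integer(round(1 / ic$dt))
    out <- matrix(0, R, N)
    for (j in seq_len(N)) {
      sim <- .em_ensemble_excitable(x / omegas[j] + xi_ex, 1L, p$alpha0,
                                    p$alpha, p$beta, p$sigma, p$n, p$m, p$K,
                                    ic$dt, nsteps, pulse_steps,
                                    rest[1], rest[2])
      out[, j] <- as.numeric(sim$ymax[, 1] > thr)
    }
    return(out)
  }
  kind <- match(p$kind, c("simple", "bistable")) - 1L
  base <- vapply(seq_len(N), function(j) .unit_baseline(p, omegas[j]),
                 numeric(1))
  y0 <- if (init == "stationary") {
    # draw each realization from the stationary law at its own signal, so
    # the ensemble starts (and must remain) stationary under integration
    vapply(seq_len(N), function(j) {
      pj <- p; pj$omega <- p$omega * omegas[j]
      if (p$kind == "bistable") {
        tb <- .fp_tables(pj)
        .fp_sample_linear(x + xi_ex, pj$K, tb$grid, tb$A0, tb$B0, tb$logq2K,
                          stats::runif(R))
      } else {
        grid <- seq(0, p$alpha0 + p$alpha + 1, length.out = 1601)
        cc <- pmax(p$alpha0 + p$alpha * .hill(x / pj$omega, p$n) + xi_ex,
                   1e-9)
        .fp_sample_simple(cc, p$K, grid, stats::runif(R))
      }
    }, numeric(R))
  } else matrix(rep(base, each = R), R, N)
  if (R == 1) y0 <- matrix(y0, 1, N)
  if (length(xi_ex) == 1) xi_ex <- rep(xi_ex, R)
  sim <- .em_ensemble_1d(kind, x, xi_ex, p$omega * omegas, cfg$crosstalk,
                         p$alpha0, p$alpha, p$n, p$K, ic$dt, nsteps, 0.2, y0)
  out <- sim$avg - matrix(rep(base, each = R), R, N)
  if (cfg$output == "binary")
    out <- matrix(as.numeric(binarize_bistable(sim$avg)), R, N)
  out
}

#' Simulate one realization of the redundant array
#'
#' Draws one shared extrinsic offset, integrates (or samples) every unit's
#' response to the signal `x`, and returns the per-unit and summed
#' responses.
#'
#' @param cfg an [array_config()].
#' @param x signal level (scalar, >= 0).
#' @param seed optional integer seed.
#' @param omegas optional fixed threshold multipliers (drawn from
#'   `cfg$heterogeneity_sd` when `NULL`).
#' @return a one-row data frame with columns `x`, `logx`, `dy_1 ... dy_N`,
#'   `dy` (`dy` is the exact sum of the per-unit responses).
#' @export
simulate_array_response <- function(cfg, x, seed = NULL, omegas = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(x) != 1 || x < 0) stop("`x` must be a single non-negative value")
  if (is.null(omegas)) omegas <- draw_unit_multipliers(cfg$N,
                                                       cfg$heterogeneity_sd)
  xi_ex <- if (cfg$extrinsic_sd > 0) stats::rnorm(1, 0, cfg$extrinsic_sd) else 0
  resp <- if (cfg$response_source == "stationary")
    .responses_stationary(cfg, x, omegas, xi_ex)
  else .responses_sde(cfg, x, omegas, xi_ex)
  out <- data.frame(x = x, logx = input_variable(x))
  for (j in seq_len(cfg$N)) out[[paste0("dy_", j)]] <- resp[1, j]
  out$dy <- sum(resp[1, ])
  out
}

#' Ensemble of (signal, response) realizations
#'
#' Runs `n_real` independent realizations of the array: a fresh signal draw
#' and fresh intrinsic/extrinsic noise per realization. Threshold
#' multipliers are drawn once per ensemble (one heterogeneous array read
#' out many times) and recorded in the attributes.
#'
#' @param cfg an [array_config()].
#' @param dist an [input_distribution()].
#' @param n_real number of realizations (default `1e4`).
#' @param seed integer seed (mandatory for reproducibility).
#' @param omegas optional fixed threshold multipliers.
#' @return data frame with columns `realization`, `x`, `logx`,
#'   `dy_1 ... dy_N`, `dy`, with attributes `config`, `omegas`, `seed`.
#' @examples
#' cfg <- array_config(N = 2, params = bistable_unit_params())
#' d <- run_ensemble(cfg, input_distribution("log10-uniform", 0.001),
#'                   n_real = 200, seed = 1)
#' stopifnot(all(abs(d$dy - (d$dy_1 + d$dy_2)) < 1e-12))
#' @export
run_ensemble <- function(cfg, dist, n_real = 1e4, seed, omegas = NULL) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (n_real < 2) stop("`n_real` must be >= 2")
  set.seed(seed)
  x <- sample_inputs(dist, n_real)
  xi_ex <- if (cfg$extrinsic_sd > 0)
    stats::rnorm(n_real, 0, cfg$extrinsic_sd) else rep(0, n_real)
  if (is.null(omegas))
    omegas <- draw_unit_multipliers(cfg$N, cfg$heterogeneity_sd)
  resp <- if (cfg$response_source == "stationary")
    .responses_stationary(cfg, x, omegas, xi_ex)
  else .responses_sde(cfg, x, omegas, xi_ex)
  out <- data.frame(realization = seq_len(n_real), x = x,
                    logx = input_variable(x))
  for (j in seq_len(cfg$N)) out[[paste0("dy_", j)]] <- resp[, j]
  out$dy <- rowSums(resp)
  attr(out, "config") <- cfg
  attr(out, "omegas") <- omegas
  attr(out, "seed") <- seed
  out
}

#' Write an ensemble with its run manifest
#'
#' Writes the tidy realization table as CSV and a JSON manifest carrying
#' the full array configuration, seed and threshold multipliers.
#'
#' @param ensemble a data frame from [run_ensemble()].
#' @param path CSV output path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(ensemble, path, row.names = FALSE)
  cfg <- attr(ensemble, "config")
  manifest <- list(
    package_version = as.character(utils::packageVersion("redinfo")),
    seed = attr(ensemble, "seed"),
    omegas = attr(ensemble, "omegas"),
    n_real = nrow(ensemble),
    config = list(N = cfg$N, params = unit_params_to_list(cfg$params),
                  extrinsic_sd = cfg$extrinsic_sd,
                  crosstalk = cfg$crosstalk,
                  heterogeneity_sd = cfg$heterogeneity_sd,
                  output = cfg$output,
                  response_source = cfg$response_source))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
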