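# Synthetic dose-response generators emulating the statistical structure of
# the two empirical analyses (a graded reporter under increasing gene copy
# number, and a Boolean all-or-none response with cell-to-cell threshold
# variability). These are synthetic stand-ins: no attempt is made to match
# the published measurements, only their structure, so the analysis stage is
# testable without any download.

.validate_dose_response <- function(tab) {
  need <- c("dose", "response", "replicate")
  if (!all(need %in% names(tab)))
    stop("dose-response table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$dose <= 0)) stop("doses must be > 0")
  if (length(unique(tab$dose)) < 2) stop("need at least 2 distinct doses")
  invisible(tab)
}

#' Synthetic graded dose-response table
#'
#' Emulates a fluorescent reporter under `N` gene copies: each observation
#' is the sum over copies of a Hill response to the dose, each copy carrying
#' independent multiplicative lognormal noise with coefficient of variation
#' `noise_cv` (mean 1). With `noise_cv = 0` the response is exactly `N`
#' times the single-copy Hill curve.
#'
#' @param N gene copy number.
#' @param doses dose grid (default: log-uniform over two decades around 1).
#' @param n_per_dose observations per dose.
#' @param noise_cv per-copy multiplicative noise CV.
#' @param ec50 Hill midpoint (default: geometric center of the dose grid).
#' @param hill_n Hill steepness.
#' @param ymax single-copy saturating response.
#' @param seed integer seed.
#' @return a dose-response data frame (`dose`, `response`, `replicate`).
#' @export
generate_graded_dose_response <- function(N, doses = 10^seq(-1, 1,
                                                            length.out = 12),
                                          n_per_dose = 50, noise_cv = 0.3,
                                          ec50 = NULL, hill_n = 2, ymax = 1,
                                          seed = 1) {
  if (N < 1 || N != round(N)) stop("`N` must be a positive integer")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  set.seed(seed)
  if (is.null(ec50)) ec50 <- exp(mean(log(range(doses))))
  base <- ymax * doses^hill_n / (ec50^hill_n + doses^hill_n)
  sdl <- sqrt(log(1 + noise_cv^2))
  rows <- lapply(seq_along(doses), function(i) {
    resp <- vapply(seq_len(n_per_dose), function(k) {
      noise <- if (noise_cv == 0) rep(1, N)
               else stats::rlnorm(N, -sdl^2 / 2, sdl)
      base[i] * sum(noise)
    }, numeric(1))
    data.frame(dose = doses[i], response = resp,
               replicate = seq_len(n_per_dose))
  })
  .validate_dose_response(do.call(rbind, rows))
}

#' Synthetic Boolean dose-response table
#'
#' Emulates an all-or-none single-cell decision (e.g. maturation) with
#' cell-to-cell variability in the response threshold: each observation
#' draws a lognormal individual threshold (median `threshold_median`,
#' coefficient of variation `threshold_cv`) and responds with 1 iff the
#' dose exceeds it. With `threshold_cv > 0`, sub-threshold doses trigger
#' responses in some individuals, degrading information transfer relative
#' to the deterministic (`threshold_cv = 0`) step.
#'
#' @param threshold_median median individual threshold.
#' @param threshold_cv threshold coefficient of variation.
#' @param doses dose grid.
#' @param n_per_dose observations per dose.
#' @param seed integer seed.
#' @return a dose-response data frame with Boolean `response`.
#' @export
generate_binary_dose_response <- function(threshold_median = 1,
                                          threshold_cv = 0.5,
                                          doses = 10^seq(-1, 1,
                                                         length.out = 12),
                                          n_per_dose = 50, seed = 1) {
  if (threshold_cv < 0) stop("`threshold_cv` must be >= 0")
  set.seed(seed)
  sdl <- sqrt(log(1 + threshold_cv^2))
  rows <- lapply(seq_along(doses), function(i) {
    thr <- if (threshold_cv == 0) rep(threshold_median, n_per_dose)
           else stats::rlnorm(n_per_dose, log(threshold_median), sdl)
    data.frame(dose = doses[i], response = as.integer(doses[i] > thr),
               replicate = seq_len(n_per_dose))
  })
  .validate_dose_response(do.call(rbind, rows))
}

#' Mutual information of a dose-response table
#'
#' MI between the log10 dose and the response. Boolean responses are
#' treated as a discrete output; continuous responses use the histogram
#' estimator. Since dose designs have few distinct levels, the input bins
#' are capped at the number of distinct doses.
#'
#' @param tab a dose-response data frame (`dose`, `response`, `replicate`),
#'   e.g. from the generators or [read_dose_response()].
#' @param cfg an [mi_config()]; a design-adapted default is built when
#'   `NULL`.
#' @return an `mi_result`.
#' @export
mi_dose_response <- function(tab, cfg = NULL) {
  .validate_dose_response(tab)
  ndose <- length(unique(tab$dose))
  if (is.null(cfg))
    cfg <- mi_config(n_bins_input = max(2, min(30, ndose)),
                     output_mode = if (all(tab$response %in% c(0, 1)))
                       "discrete" else "continuous")
  mutual_information(input_variable(tab$dose), tab$response, cfg)
}

#' Read and write dose-response tables
#'
#' CSV interface (columns `dose`, `response`, `replicate`); the reader
#' validates the table invariants.
#'
#' @param tab a dose-response data frame.
#' @param path CSV file path.
#' @return `write_dose_response()`: `path`, invisibly;
#'   `read_dose_response()`: the validated data frame.
#' @export
write_dose_response <- function(tab, path) {
  .validate_dose_response(tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  .validate_dose_response(utils::read.csv(path))
}
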