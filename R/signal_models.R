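#' Input signal distributions
#'
#' Specification of the stochastic input signal `x`. All three families are
#' parameterized on the log10 scale around a central signal level `mean`
#' (the geometric center of the support):
#'
#' * `"log10-uniform"`: `x = mean * 10^u` with `u ~ U[-span/2, +span/2]`
#'   (default span 2, i.e. two orders of magnitude).
#' * `"lognormal"`: `log10(x) ~ Normal(log10(mean), shape)` with default
#'   `shape = 2/3`.
#' * `"log-beta"`: `log10(x) = log10(mean) + span*(B - 1/2)` with
#'   `B ~ Beta(shape, shape)` and default `shape = 1/3`, which piles mass at
#'   the edges of the two-decade support (bimodal in log scale).
#'
#' @param family one of `"log10-uniform"`, `"lognormal"`, `"log-beta"`.
#' @param mean central signal level (geometric center of the log support).
#' @param shape family-specific shape: sd of `log10(x)` for the lognormal,
#'   the common Beta shape parameter for the log-beta; ignored for the
#'   uniform.
#' @param span width of the log10 support in decades (uniform and log-beta).
#' @return an `input_distribution` object.
#' @examples
#' d <- input_distribution("log10-uniform", mean = 0.001)
#' range(sample_inputs(d, 1000, seed = 1))
#' @export
input_distribution <- function(family = c("log10-uniform", "lognormal",
                                          "log-beta"),
                               mean = 1, shape = NULL, span = 2) {
  family <- match.arg(family)
  if (mean <= 0) stop("`mean` must be > 0")
  if (span <= 0) stop("`span` must be > 0")
  if (is.null(shape))
    shape <- switch(family, lognormal = 2 / 3, `log-beta` = 1 / 3, NA_real_)
  if (!is.na(shape) && shape <= 0) stop("`shape` must be > 0")
  structure(list(family = family, mean = mean, shape = shape, span = span),
            class = "input_distribution")
}

#' @export
print.input_distribution <- function(x, ...) {
  cat(sprintf("<input_distribution> %s, mean %g, shape %s, span %g decades\n",
              x$family, x$mean, format(x$shape), x$span))
  invisible(x)
}

#' Sample input signals
#'
#' Draws `n` signal values from an [input_distribution()]. All samples are
#' strictly positive.
#'
#' @param dist an `input_distribution`.
#' @param n number of draws.
#' @param seed optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return numeric vector of signal values.
#' @export
sample_inputs <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "input_distribution"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lmean <- log10(dist$mean)
  l <- switch(dist$family,
    `log10-uniform` = lmean + stats::runif(n, -dist$span / 2, dist$span / 2),
    lognormal = stats::rnorm(n, lmean, dist$shape),
    `log-beta` = lmean + dist$span *
      (stats::rbeta(n, dist$shape, dist$shape) - 0.5))
  10^l
}

#' Input variable for information calculations
#'
#' The input variable used for mutual information is `log10(x)`. Mutual
#' information is invariant under any strictly monotone transform of the
#' input, so the base is a convention; base 10 matches the `10^u` signal
#' parameterization.
#'
#' @param x signal values (> 0).
#' @return `log10(x)`.
#' @export
input_variable <- function(x) {
  if (any(x <= 0)) stop("`x` must be > 0")
  log10(x)
}
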