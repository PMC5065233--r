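#' Mutual-information estimator settings
#'
#' The default estimator is the histogram plug-in: a joint histogram of the
#' binned input (`log10 x`, equal-width bins over the observed range) and
#' the output. Discrete outputs (Boolean or Boolean sums) use their exact
#' support as bins, so the plug-in estimate coincides with the closed-form
#' discrete mutual information of the empirical table.
#'
#' @param estimator only `"histogram"` is implemented.
#' @param n_bins_input number of equal-width input bins (>= 2).
#' @param n_bins_output number of equal-width output bins for continuous
#'   outputs (>= 2).
#' @param output_mode `"auto"` treats outputs with at most 12 distinct
#'   values as discrete; `"continuous"` and `"discrete"` force the mode.
#' @param input_binning `"width"` (equal-width bins, the default) or
#'   `"quantile"` (equal-mass bins). Quantile binning converges faster for
#'   deterministic channels, where the single bin straddling a threshold
#'   carries all of the conditional entropy, and makes the estimate exactly
#'   invariant under monotone input transforms.
#' @param bias_correction `"none"` (plain plug-in, exact on empirical
#'   tables) or `"mm"`, a Miller-Madow-style guard subtracting the
#'   first-order finite-sample bias `(cells - rows - cols + 1)/(2 n ln 2)`
#'   (counting occupied bins), clipped at zero. The guard drives the
#'   estimate for independent samples to ~0 at the default settings.
#' @return an `mi_config` object.
#' @export
mi_config <- function(estimator = "histogram", n_bins_input = 30,
                      n_bins_output = 30,
                      output_mode = c("auto", "continuous", "discrete"),
                      input_binning = c("width", "quantile"),
                      bias_correction = c("none", "mm")) {
  estimator <- match.arg(estimator, "histogram")
  output_mode <- match.arg(output_mode)
  input_binning <- match.arg(input_binning)
  bias_correction <- match.arg(bias_correction)
  if (n_bins_input < 2 || n_bins_output < 2)
    stop("bin counts must be >= 2")
  structure(list(estimator = estimator, n_bins_input = n_bins_input,
                 n_bins_output = n_bins_output, output_mode = output_mode,
                 input_binning = input_binning,
                 bias_correction = bias_correction),
            class = "mi_config")
}

.bin_quantile <- function(v, nb) {
  br <- unique(stats::quantile(v, seq(0, 1, length.out = nb + 1)))
  if (length(br) < 3) return(rep(1L, length(v)))
  pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L),
       length(br) - 1L)
}

.bin_equal_width <- function(v, nb) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  br <- seq(r[1], r[2], length.out = nb + 1)
  pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), nb)
}

#' Mutual information between input and output samples
#'
#' Plug-in estimate of `I(log x; Delta y)` in bits from paired samples:
#' `I = sum p(a,b) log2[p(a,b) / (p(a) p(b))]` over the joint histogram.
#' Degenerate samples (constant input or output) give 0 bits with a
#' `degenerate` flag. Small negative values cannot arise from the plug-in
#' on a shared binning, but are clipped to 0 defensively.
#'
#' @param logx input variable samples (already on the log scale).
#' @param y output samples (`Delta y`, Boolean sums, ...).
#' @param cfg an [mi_config()].
#' @return an `mi_result`: list with `bits`, `n`, `config`, `flags`.
#' @examples
#' set.seed(1)
#' x <- runif(5000); y <- as.numeric(x > 0.5)
#' mutual_information(x, y)$bits  # ~1 bit
#' @export
mutual_information <- function(logx, y, cfg = mi_config()) {
  if (length(logx) != length(y)) stop("`logx` and `y` must have equal length")
  n <- length(logx)
  if (n < 100)
    warning("fewer than 100 samples: the plug-in estimate will be biased")
  flags <- character(0)
  if (length(unique(logx)) == 1 || length(unique(y)) == 1) {
    return(structure(list(bits = 0, n = n, config = cfg,
                          flags = "degenerate"), class = "mi_result"))
  }
  ix <- if (identical(cfg$input_binning, "quantile"))
    .bin_quantile(logx, cfg$n_bins_input)
  else .bin_equal_width(logx, cfg$n_bins_input)
  discrete <- switch(cfg$output_mode,
                     discrete = TRUE, continuous = FALSE,
                     auto = length(unique(y)) <= 12)
  iy <- if (discrete) match(y, sort(unique(y)))
        else .bin_equal_width(y, cfg$n_bins_output)
  p <- table(ix, iy) / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  bits <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  if (identical(cfg$bias_correction, "mm")) {
    bias <- (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * n * log(2))
    bits <- bits - bias
    flags <- c(flags, "mm_corrected")
  }
  if (bits < 0) { flags <- c(flags, "clipped_negative"); bits <- 0 }
  structure(list(bits = bits, n = n, config = cfg, flags = flags,
                 discrete_output = discrete),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("MI = %.4f bits (n = %d, %s output%s)\n", x$bits, x$n,
              if (isTRUE(x$discrete_output)) "discrete" else "binned",
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Serialize an MI result to JSON
#'
#' @param x an `mi_result`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string or `path`.
#' @export
mi_result_json <- function(x, path = NULL) {
  obj <- list(bits = x$bits, n = x$n, flags = x$flags,
              estimator = x$config$estimator,
              n_bins_input = x$config$n_bins_input,
              n_bins_output = x$config$n_bins_output,
              output_mode = x$config$output_mode)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Relative mutual information
#'
#' Ratio of an MI estimate to a reference estimate (e.g. the `N = 1`
#' system).
#'
#' @param mi,mi_ref `mi_result` objects or plain numbers (bits).
#' @return `mi / mi_ref`.
#' @export
relative_mi <- function(mi, mi_ref) {
  v <- if (inherits(mi, "mi_result")) mi$bits else mi
  r <- if (inherits(mi_ref, "mi_result")) mi_ref$bits else mi_ref
  if (r <= 0) stop("reference MI is zero: relative MI undefined")
  v / r
}

#' Distance of the averaged response from the ideal linear response
#'
#' Bins the input, averages the response per bin, fits a least-squares line
#' through the bin means, and reports the root-mean-square deviation of the
#' means from that line, normalized by the range of the mean response. A
#' perfectly linear averaged stimulus-response profile gives 0; a sharp
#' step gives the largest values.
#'
#' @param logx input samples (log scale).
#' @param dy response samples.
#' @param n_bins number of input bins.
#' @return normalized RMS distance (scalar).
#' @export
linearity_distance <- function(logx, dy, n_bins = 30) {
  ib <- .bin_equal_width(logx, n_bins)
  xm <- tapply(logx, ib, mean)
  ym <- tapply(dy, ib, mean)
  if (length(ym) < 3) stop("fewer than 3 non-empty input bins")
  fit <- stats::lm.fit(cbind(1, xm), ym)
  rng <- diff(range(ym))
  if (rng == 0) return(0)
  sqrt(mean(fit$residuals^2)) / rng
}
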