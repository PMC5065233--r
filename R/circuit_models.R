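#' Parameter sets for the threshold regulatory units
#'
#' Constructors for the biochemical parameter sets of the three dynamical
#' threshold units (dimensionless models) and the idealized Heaviside unit.
#' All rates are in units of the protein decay rate, expression levels are
#' scaled by the effective transcription-factor dissociation constant, and
#' `K` is the molecule-number scale that sets the amplitude of intrinsic
#' noise (amplitude ~ 1/sqrt(K)).
#'
#' * `simple_unit_params()`: a gene whose production is a Hill function of
#'   the signal `x`, `dy/dt = alpha0 + alpha x^n/(1+x^n) - y`.
#' * `bistable_unit_params()`: transcriptional autoactivation,
#'   `dy/dt = alpha0 + alpha y^n/(1+y^n) - y + x`, with the signal entering
#'   as a small additive perturbation.
#' * `excitable_unit_params()`: a two-gene competence-like excitable circuit
#'   with interlinked positive and negative feedback (see
#'   [excitable_drift_diffusion()]).
#'
#' `omega` is a heterogeneity multiplier on the unit's dissociation scale:
#' Hill arguments are evaluated at `y/omega` (bistable) or `x/omega`
#' (simple), so `omega > 1` shifts the activation threshold up.
#'
#' @param alpha0 basal expression rate.
#' @param alpha maximal regulated expression rate.
#' @param n Hill steepness of the activation.
#' @param K molecule-number scale; intrinsic noise amplitude scales as
#'   `1/sqrt(K)`.
#' @param omega heterogeneity multiplier of the dissociation scale
#'   (default 1, homogeneous).
#' @return An object of class `unit_params` (a named list with a `kind`
#'   field).
#' @examples
#' p <- bistable_unit_params()
#' bistable_drift_diffusion(1, 0, p)
#' @export
simple_unit_params <- function(alpha0 = 0.01, alpha = 2.5, n = 2, K = 100,
                               omega = 1) {
  .check_pos(c(alpha0 = alpha0, alpha = alpha, K = K, omega = omega))
  if (n < 1) stop("Hill steepness `n` must be >= 1")
  structure(list(kind = "simple", alpha0 = alpha0, alpha = alpha, n = n,
                 K = K, omega = omega), class = "unit_params")
}

#' @rdname simple_unit_params
#' @export
bistable_unit_params <- function(alpha0 = 0.01, alpha = 2.5, n = 2, K = 100,
                                 omega = 1) {
  .check_pos(c(alpha0 = alpha0, alpha = alpha, K = K, omega = omega))
  if (n < 1) stop("Hill steepness `n` must be >= 1")
  structure(list(kind = "bistable", alpha0 = alpha0, alpha = alpha, n = n,
                 K = K, omega = omega), class = "unit_params")
}

#' @rdname simple_unit_params
#' @param beta maximal expression rate of the second (repressed) gene.
#' @param sigma dissociation-constant ratio of the excitable circuit.
#' @param m Hill steepness of the repression.
#' @export
excitable_unit_params <- function(alpha0 = 0.004, alpha = 0.07, beta = 0.826,
                                  sigma = 5, n = 2, m = 5, K = 500) {
  .check_pos(c(alpha0 = alpha0, alpha = alpha, beta = beta, sigma = sigma,
               K = K))
  if (n < 1 || m < 1) stop("Hill steepnesses must be >= 1")
  structure(list(kind = "excitable", alpha0 = alpha0, alpha = alpha,
                 beta = beta, sigma = sigma, n = n, m = m, K = K),
            class = "unit_params")
}

#' @rdname simple_unit_params
#' @param theta threshold of the Heaviside unit.
#' @param noise_sd standard deviation of the unit's independent additive
#'   noise.
#' @export
heaviside_unit_params <- function(theta = 1, noise_sd = 0) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(kind = "heaviside", theta = theta, noise_sd = noise_sd),
            class = "unit_params")
}

.check_pos <- function(x) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("parameter(s) must be positive: ", paste(names(x)[bad], collapse = ", "))
}

#' @export
print.unit_params <- function(x, ...) {
  cat("<unit_params:", x$kind, "> ",
      paste(sprintf("%s=%g", setdiff(names(x), "kind"),
                    unlist(x[setdiff(names(x), "kind")])), collapse = ", "),
      "\n")
  invisible(x)
}

# Hill activation u^n/(1+u^n), safely 0 at u <= 0
.hill <- function(u, n) {
  u <- pmax(u, 0)
  p <- u^n
  p / (1 + p)
}

#' Drift and noise amplitude of the simple regulated unit
#'
#' Langevin terms of the simple unit: drift
#' `alpha0 + alpha x^n/(1+x^n) - y` and multiplicative noise amplitude
#' `q = sqrt((alpha0 + alpha x^n/(1+x^n) + y)/K)`, the square root of the
#' summed reaction propensities over the molecule-number scale.
#'
#' @param y expression level (>= 0); vectorized.
#' @param x signal level (>= 0).
#' @param p a `unit_params` object from [simple_unit_params()].
#' @return list with components `drift` and `q`.
#' @export
simple_drift_diffusion <- function(y, x, p = simple_unit_params()) {
  if (any(y < 0) || any(x < 0)) stop("`y` and `x` must be non-negative")
  prod <- p$alpha0 + p$alpha * .hill(x / p$omega, p$n)
  list(drift = prod - y, q = sqrt((prod + y) / p$K))
}

#' Drift and noise amplitude of the bistable autoactivating unit
#'
#' Langevin terms of the positive-feedback unit: drift
#' `alpha0 + alpha y^n/(1+y^n) - y + x` with the signal as an additive
#' perturbation, and `q = sqrt((alpha0 + alpha y^n/(1+y^n) + y)/K)`; the
#' small signal is neglected in the propensity sum.
#'
#' @inheritParams simple_drift_diffusion
#' @param p a `unit_params` object from [bistable_unit_params()].
#' @return list with components `drift` and `q`.
#' @export
bistable_drift_diffusion <- function(y, x, p = bistable_unit_params()) {
  if (any(y < 0)) stop("`y` must be non-negative")
  prod <- p$alpha0 + p$alpha * .hill(y / p$omega, p$n)
  list(drift = prod - y + x, q = sqrt((prod + y) / p$K))
}

#' Drift and noise amplitude of the excitable competence-like unit
#'
#' Two-variable excitable circuit with interlinked feedbacks and shared
#' enzymatic degradation:
#' \deqn{dy/dt = \alpha_0 + \alpha (\sigma y)^n/(1+(\sigma y)^n) - y/(1+y+z)}
#' \deqn{dz/dt = \beta/(1+\sigma y^m) - z/(1+y+z) + x}
#' The positive-feedback Hill argument is \eqn{\sigma y} (dissociation
#' constant \eqn{1/\sigma}), as in the dimensionless competence model the
#' unit is patterned on; with the stated parameters this places the
#' deterministic pulse-excitation threshold near `x = 0.9`. Noise of
#' constant amplitude `q = sqrt((beta+1)/K)` acts on the `z` equation only.
#'
#' @param state numeric vector `c(y, z)` (or a 2-column matrix).
#' @param x signal level.
#' @param p a `unit_params` object from [excitable_unit_params()].
#' @return list with components `drift` (`dy`, `dz`) and `q` (scalar).
#' @export
excitable_drift_diffusion <- function(state, x, p = excitable_unit_params()) {
  if (is.matrix(state)) { y <- state[, 1]; z <- state[, 2] }
  else { y <- state[1]; z <- state[2] }
  if (any(y < 0) || any(z < 0)) stop("state must be non-negative")
  den <- 1 + y + z
  dy <- p$alpha0 + p$alpha * .hill(p$sigma * y, p$n) - y / den
  dz <- p$beta / (1 + p$sigma * pmax(y, 0)^p$m) - z / den + x
  list(drift = cbind(dy = dy, dz = dz), q = sqrt((p$beta + 1) / p$K))
}

# drift of a 1-D unit as a plain function of y (internal)
.drift_1d <- function(y, x, p) {
  switch(p$kind,
         simple = simple_drift_diffusion(pmax(y, 0), x, p)$drift,
         bistable = bistable_drift_diffusion(pmax(y, 0), x, p)$drift,
         stop("not a 1-D unit: ", p$kind))
}

#' Deterministic fixed points of a unit
#'
#' Finds all roots of the deterministic drift at a fixed signal level,
#' tagged stable/unstable by linearization. For the 1-D units the search
#' interval is `[0, alpha0 + alpha + x + 1]` (the drift is negative beyond
#' the production maximum); for the excitable unit a grid-seeded Newton
#' search covers the physiological box `y` in `[0, 1.5]`, `z` in `[0, 8]`.
#'
#' @param kind `"simple"`, `"bistable"` or `"excitable"` (taken from `p` if
#'   missing).
#' @param p a `unit_params` object.
#' @param x signal level (>= 0).
#' @return data frame with columns `y` (and `z` for the excitable unit) and
#'   `stable`, sorted by `y`.
#' @examples
#' deterministic_fixed_points(p = bistable_unit_params(), x = 0)
#' @export
deterministic_fixed_points <- function(kind = NULL, p, x = 0) {
  if (is.null(kind)) kind <- p$kind
  if (x < 0) stop("`x` must be >= 0")
  if (kind %in% c("simple", "bistable")) {
    upper <- p$alpha0 + p$alpha + x + 1
    g <- seq(0, upper, length.out = 4001)
    d <- .drift_1d(g, x, p)
    sgn <- which(diff(sign(d)) != 0)
    roots <- vapply(sgn, function(i)
      stats::uniroot(function(y) .drift_1d(y, x, p), c(g[i], g[i + 1]),
                     tol = 1e-12)$root, numeric(1))
    # boundary roots where drift exactly zero at a grid point
    roots <- sort(unique(c(roots, g[d == 0])))
    h <- 1e-7
    stab <- vapply(roots, function(r)
      (.drift_1d(r + h, x, p) - .drift_1d(max(r - h, 0), x, p)) < 0,
      logical(1))
    return(data.frame(y = roots, stable = stab))
  }
  if (kind != "excitable") stop("unknown kind: ", kind)
  f <- function(s) as.numeric(excitable_drift_diffusion(pmax(s, 0), x, p)$drift)
  seeds <- expand.grid(y = seq(0.01, 1.5, length.out = 12),
                       z = seq(0.05, 8, length.out = 12))
  found <- NULL
  for (i in seq_len(nrow(seeds))) {
    s <- as.numeric(seeds[i, ])
    ok <- TRUE
    for (it in 1:60) {
      f0 <- f(s)
      J <- .num_jacobian(f, s)
      step <- tryCatch(solve(J, f0), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      s <- pmax(s - step, 0)
      if (max(abs(f0)) < 1e-11) break
    }
    if (!ok || max(abs(f(s))) > 1e-8) next
    if (s[1] > 2 || s[2] > 12) next
    if (is.null(found) ||
        !any(sqrt(colSums((t(found) - s)^2)) < 1e-5))
      found <- rbind(found, s)
  }
  if (is.null(found)) return(data.frame(y = numeric(0), z = numeric(0),
                                        stable = logical(0)))
  found <- found[order(found[, 1]), , drop = FALSE]
  stab <- apply(found, 1, function(s)
    all(Re(eigen(.num_jacobian(f, as.numeric(s)),
                 only.values = TRUE)$values) < -1e-9))
  data.frame(y = found[, 1], z = found[, 2], stable = stab,
             row.names = NULL)
}

.num_jacobian <- function(f, s, h = 1e-7) {
  f0 <- f(s)
  vapply(seq_along(s), function(j) {
    sp <- s; sp[j] <- sp[j] + h
    (f(sp) - f0) / h
  }, numeric(length(f0)))
}

#' Saddle-node signal threshold of the bistable unit
#'
#' The smallest signal `x` at which the low stable branch of the bistable
#' unit disappears (saddle-node bifurcation), located by bisection on the
#' number of deterministic fixed points. Note that for the default
#' parameters this deterministic threshold (~0.095) is far above the
#' *stochastic* switching threshold returned by [switching_threshold()]
#' (~0.001): with a noisy unit the relevant scale for signal discrimination
#' is where the two wells of the stationary potential balance, not where
#' the low state ceases to exist.
#'
#' @param p a `unit_params` object of kind `"bistable"`.
#' @param tol bisection tolerance on `x`.
#' @param x_upper upper end of the bisection bracket.
#' @return The saddle-node value of `x`, or `NA` with a warning if the unit
#'   is not bistable at `x = 0`.
#' @seealso [switching_threshold()]
#' @export
bifurcation_threshold <- function(p = bistable_unit_params(), tol = 1e-6,
                                  x_upper = 1) {
  if (p$kind != "bistable") stop("saddle-node threshold requires a bistable unit")
  nroots <- function(x) nrow(deterministic_fixed_points(p = p, x = x))
  if (nroots(0) < 3) {
    warning("unit is not bistable at x = 0: no threshold")
    return(NA_real_)
  }
  lo <- 0; hi <- x_upper
  if (nroots(hi) >= 3) stop("still bistable at x_upper; increase `x_upper`")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nroots(mid) >= 3) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Response of an idealized Heaviside threshold unit
#'
#' `1` if `x + xi >= theta`, else `0` (ties count as crossings).
#'
#' @param x signal value(s).
#' @param p a `unit_params` object from [heaviside_unit_params()].
#' @param xi realized additive noise value(s) (default 0).
#' @return integer 0/1 vector.
#' @export
heaviside_response <- function(x, p = heaviside_unit_params(), xi = 0) {
  as.integer(x + xi >= p$theta)
}

#' Serialize unit parameters to and from a flat list
#'
#' Flat named-list representation (`model` plus numeric fields) used in run
#' configuration files.
#'
#' @param p a `unit_params` object.
#' @return `unit_params_to_list()`: a plain named list;
#'   `unit_params_from_list()`: a `unit_params` object.
#' @export
unit_params_to_list <- function(p) {
  out <- unclass(p)
  names(out)[names(out) == "kind"] <- "model"
  out
}

#' @rdname unit_params_to_list
#' @param x a flat list with a `model` field as produced by
#'   `unit_params_to_list()`.
#' @export
unit_params_from_list <- function(x) {
  model <- x$model
  x$model <- NULL
  fn <- switch(model,
               simple = simple_unit_params,
               bistable = bistable_unit_params,
               excitable = excitable_unit_params,
               heaviside = heaviside_unit_params,
               stop("unknown model: ", model))
  do.call(fn, x)
}
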