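# Independent oracles used across the suite.

# closed-form discrete mutual information of a joint probability table
closed_form_mi <- function(p) {
  p <- p / sum(p)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  s
}

# exact sample realization of a joint count table as paired label vectors
table_to_samples <- function(counts) {
  ij <- which(counts > 0, arr.ind = TRUE)
  x <- rep(ij[, 1], counts[counts > 0])
  y <- rep(ij[, 2], counts[counts > 0])
  list(x = as.numeric(x), y = as.numeric(y))
}

# deterministic ODE endpoint via deSolve (independent of the package's
# Euler-Maruyama path)
ode_endpoint <- function(p, x, y0, t_end = 200) {
  rhs <- function(t, y, parms) {
    d <- switch(p$kind,
      simple = simple_drift_diffusion(max(y, 0), x, p)$drift,
      bistable = bistable_drift_diffusion(max(y, 0), x, p)$drift)
    list(d)
  }
  out <- deSolve::ode(y = y0, times = c(0, t_end), func = rhs, parms = NULL)
  unname(out[nrow(out), 2])
}

# roots of the bistable drift as polynomial roots (cubic oracle, n = 2):
# y^3 - (alpha0 + alpha + x) y^2 + y - (alpha0 + x) = 0
bistable_cubic_roots <- function(alpha0 = 0.01, alpha = 2.5, x = 0) {
  r <- polyroot(c(-(alpha0 + x), 1, -(alpha0 + alpha + x), 1))
  sort(Re(r[abs(Im(r)) < 1e-8]))
}

# trapezoid integral
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# empirical KS distance between samples and a tabulated density
ks_to_density <- function(samples, dens) {
  cdf <- cumsum(dens$density)
  cdf <- cdf / cdf[length(cdf)]
  ecdf_at <- ecdf(samples)(dens$y)
  max(abs(ecdf_at - cdf))
}
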