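# Stationary Fokker-Planck machinery for the 1-D units.
#
# For the bistable unit the signal enters the drift additively, so the Ito
# stationary log-density on a grid splits as
#   log P(y; x) = K*(A0(y) + x*B0(y)) - log q^2(y) + const,
# with A0, B0 cumulative integrals that are computed once per parameter set.
# This makes per-realization sampling of steady-state responses cheap and
# exact at any noise level, including regimes where barrier crossing is far
# too slow for direct Langevin simulation.

.trapz_cum <- function(g, v) {
  m <- length(g)
  cumsum(c(0, (v[-1] + v[-m]) / 2 * diff(g)))
}

# Tabulated potential pieces for a 1-D unit.
# shift: additive shift of the Hill argument (cross-talk contribution).
.fp_tables <- function(p, shift = 0, ymax = NULL, n_grid = 1601) {
  stopifnot(p$kind == "bistable")
  if (is.null(ymax)) ymax <- p$alpha0 + p$alpha + 1
  g <- seq(0, ymax, length.out = n_grid)
  prod <- p$alpha0 + p$alpha * .hill((g + shift) / p$omega, p$n)
  D <- prod + g                       # K * q^2
  list(grid = g,
       A0 = .trapz_cum(g, 2 * (prod - g) / D),
       B0 = .trapz_cum(g, 2 / D),
       logq2K = log(D),
       prod = prod)
}

# log unnormalized stationary density at signal x on the table grid
.fp_logdens <- function(tb, x, K) K * (tb$A0 + x * tb$B0) - tb$logq2K

#' Stationary Fokker-Planck density of a 1-D unit
#'
#' Ito stationary solution `P(y) ~ exp(2 int drift/q^2 dy) / q^2(y)` of the
#' chemical-Langevin model at a fixed signal level, normalized on the grid
#' `[0, y_max]`.
#'
#' @param kind `"simple"` or `"bistable"` (taken from `p` if `NULL`).
#' @param p a `unit_params` object.
#' @param x signal level.
#' @param y_max upper end of the density grid (default
#'   `alpha0 + alpha + x + 1`).
#' @param n_grid number of grid points.
#' @return data frame with columns `y` and `density` (integrates to 1).
#' @examples
#' d <- stationary_density_fp(p = bistable_unit_params(), x = 0)
#' sum(diff(d$y) * (d$density[-1] + d$density[-nrow(d)]) / 2)
#' @export
stationary_density_fp <- function(kind = NULL, p, x, y_max = NULL,
                                  n_grid = 1601) {
  if (is.null(kind)) kind <- p$kind
  if (!kind %in% c("simple", "bistable"))
    stop("stationary density is available for 1-D units only")
  if (is.null(y_max)) y_max <- p$alpha0 + p$alpha + x + 1
  g <- seq(0, y_max, length.out = n_grid)
  if (kind == "bistable") {
    prod <- p$alpha0 + p$alpha * .hill(g / p$omega, p$n)
    D <- prod + g
    ld <- p$K * (.trapz_cum(g, 2 * (prod - g + x) / D)) - log(D / p$K)
  } else {
    cc <- p$alpha0 + p$alpha * .hill(x / p$omega, p$n)
    ld <- 2 * p$K * (2 * cc * log((cc + g) / cc) - g) - log((cc + g) / p$K)
  }
  w <- exp(ld - max(ld))
  Z <- sum((w[-1] + w[-n_grid]) / 2 * diff(g))
  if (!is.finite(Z) || Z <= 0 || w[n_grid] > 1e-6 * max(w))
    stop("density not normalizable on [0, ", y_max, "]; increase y_max")
  data.frame(y = g, density = w / Z)
}

#' Effective stochastic potential of a 1-D unit
#'
#' `phi(y) = -log P_st(y)` up to an additive constant, where `P_st` is the
#' stationary Fokker-Planck density. When the potential has two wells the
#' barrier height is reported as the potential at the intervening maximum
#' minus the higher (shallower) of the two well minima, i.e. the smaller
#' escape barrier.
#'
#' @inheritParams stationary_density_fp
#' @return list with `y`, `phi`, `minima` (data frame of well locations and
#'   depths), `bistable` flag, and `barrier` (NA when single-welled).
#' @export
effective_potential <- function(kind = NULL, p, x, y_max = NULL,
                                n_grid = 1601) {
  d <- stationary_density_fp(kind, p, x, y_max, n_grid)
  phi <- -log(pmax(d$density, 1e-300))
  n <- length(phi)
  int <- 2:(n - 1)
  imin <- int[phi[int] < phi[int - 1] & phi[int] <= phi[int + 1]]
  imax <- int[phi[int] > phi[int - 1] & phi[int] >= phi[int + 1]]
  if (phi[1] < phi[2]) imin <- c(1L, imin)
  minima <- data.frame(y = d$y[imin], phi = phi[imin])
  bist <- nrow(minima) >= 2
  barrier <- NA_real_
  if (bist) {
    two <- minima[order(minima$phi), ][1:2, ]
    lo <- min(two$y); hi <- max(two$y)
    sad <- max(phi[d$y > lo & d$y < hi])
    barrier <- sad - max(two$phi)
  }
  list(y = d$y, phi = phi, minima = minima, bistable = bist,
       barrier = barrier)
}

#' Stochastic switching threshold of the bistable unit
#'
#' The signal level at which the two wells of the stationary potential have
#' equal depth, i.e. where the zero-noise limit of the stationary density
#' flips from the OFF to the ON state. The equal-depth condition
#' `int drift/q^2 dy = 0` between the outer fixed points is independent of
#' the molecule-number scale `K`. For the default parameters this gives
#' `x* ~ 0.00117`, the threshold at which a uniform-in-log signal centered
#' on it elicits ON and OFF with equal probability (one bit noiseless).
#'
#' @param p a bistable `unit_params` object.
#' @param tol bisection tolerance.
#' @return the switching threshold `x*`, or `NA` with a warning when the
#'   unit is not bistable at `x = 0` or the OFF well is never the deeper
#'   one.
#' @seealso [bifurcation_threshold()] for the deterministic saddle-node.
#' @export
switching_threshold <- function(p = bistable_unit_params(), tol = 1e-8) {
  if (p$kind != "bistable") stop("switching threshold requires a bistable unit")
  depth_gap <- function(x) {
    fp <- deterministic_fixed_points(p = p, x = x)
    if (nrow(fp) < 3) return(NA_real_)
    f <- function(y) {
      prod <- p$alpha0 + p$alpha * .hill(y / p$omega, p$n)
      (prod - y + x) / (prod + y)
    }
    stats::integrate(f, fp$y[1], fp$y[3], rel.tol = 1e-10)$value
  }
  g0 <- depth_gap(0)
  if (is.na(g0)) { warning("unit is not bistable at x = 0"); return(NA_real_) }
  if (g0 >= 0) { warning("ON well already deeper at x = 0"); return(NA_real_) }
  lo <- 0; hi <- 1e-3
  while (TRUE) {
    gh <- depth_gap(hi)
    if (is.na(gh) || gh > 0) break
    lo <- hi; hi <- hi * 2
    if (hi > 1) { warning("no equal-depth point found"); return(NA_real_) }
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- depth_gap(mid)
    if (!is.na(gm) && gm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---------------------------------------------------------------------------
# Mean first-passage times and the two-state reduction used for cross-talk.

# Unit structure on a grid: log-density, roots, well masses/means, and
# Kramers rates (1/MFPT) between wells. `shift` is the cross-talk
# contribution to the Hill argument; `x` the signal.
.unit_twostate <- function(p, x, shift = 0, n_grid = 1201) {
  tb <- .fp_tables(p, shift = shift, n_grid = n_grid)
  g <- tb$grid
  drift <- tb$prod - g + x
  ld <- p$K * (tb$A0 + x * tb$B0) - tb$logq2K
  w <- exp(ld - max(ld))
  sgn <- which(diff(sign(drift)) != 0)
  roots <- g[sgn]
  h <- g[2] - g[1]
  if (length(roots) < 3) {
    on <- roots[1] > 1
    mean_y <- sum(w * g) / sum(w)
    return(list(mono = TRUE, on = on,
                means = if (on) c(NA, mean_y) else c(mean_y, NA),
                grid = g, w = w, split = if (on) 1L else length(g)))
  }
  isplit <- sgn[2]
  lo <- seq_len(isplit); hi <- (isplit + 1):length(g)
  m0 <- sum((w * g)[lo]) / sum(w[lo])
  m1 <- sum((w * g)[hi]) / sum(w[hi])
  D <- (tb$prod + g) / p$K                       # q^2
  rho <- w
  cumf <- cumsum(rho) * h
  cumb <- rev(cumsum(rev(rho))) * h
  ia <- which.min(abs(g - roots[1]))
  ib <- isplit
  ic <- which.min(abs(g - roots[3]))
  T01 <- sum((2 / (D * rho) * cumf)[ia:ib]) * h   # OFF -> barrier top
  T10 <- sum((2 / (D * rho) * cumb)[ib:ic]) * h   # ON  -> barrier top
  list(mono = FALSE, means = c(m0, m1), grid = g, w = w, split = isplit,
       r01 = 1 / T01, r10 = 1 / T10)
}

# Stationary distribution of a 4-state single-flip Markov chain on the
# square 00-10-11-01 via the Markov-chain tree theorem (robust to rate
# ratios of hundreds of orders of magnitude; zero rates allowed).
# lr: 8 log-rates named by directed edge.
.pair_tree_stationary <- function(lr) {
  # vertices: 1=(0,0) 2=(1,0) 3=(0,1) 4=(1,1)
  edges <- list(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(2L, 4L))
  # directed log-rates for each edge (forward = first->second, back = reverse)
  fwd <- lr[c("r1_on_s20", "r1_on_s21", "r2_on_s10", "r2_on_s11")]
  bwd <- lr[c("r1_off_s20", "r1_off_s21", "r2_off_s10", "r2_off_s11")]
  logpi <- rep(-Inf, 4)
  for (drop in 1:4) {
    keep <- setdiff(1:4, drop)
    # adjacency of the remaining tree (a path)
    adj <- lapply(1:4, function(v) integer(0))
    for (e in keep) for (k in 1:2) {
      v <- edges[[e]][k]
      adj[[v]] <- c(adj[[v]], e)
    }
    for (root in 1:4) {
      # orient each kept edge toward the root: BFS from root
      lp <- 0
      parent <- rep(NA_integer_, 4); parent[root] <- 0L
      queue <- root
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (e in adj[[v]]) {
          o <- setdiff(edges[[e]], v)
          if (is.na(parent[o])) {
            parent[o] <- v
            # edge oriented o -> v
            lp <- lp + if (edges[[e]][1] == o) fwd[e] else bwd[e]
            queue <- c(queue, o)
          }
        }
      }
      logpi[root] <- .logsumexp(c(logpi[root], lp))
    }
  }
  pi <- exp(logpi - max(logpi))
  pi / sum(pi)
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Stationary channel for a cross-talked bistable pair, precomputed on a
# grid of signal values. Unit 1's Hill argument is y1 + eps2*y2, unit 2's
# is y2 + eps1*y1; the partner is frozen at its conditional well mean
# (adiabatic reduction, justified by the huge time-scale separation between
# intra-well relaxation, O(1), and barrier crossing, O(exp(K*dpsi))).
.crosstalk_channel <- function(p, eps1, eps2, x_grid, n_grid = 1201) {
  # relaxation-rate scale used when a conditional well has disappeared
  fast <- log(1)
  lapply(x_grid, function(x) {
    m <- matrix(c(0.0103, 2.02, 0.0103, 2.02), 2, 2)  # [state+1, unit]
    U1 <- U2 <- NULL
    for (it in 1:2) {
      U1 <- lapply(1:2, function(s2)        # unit 1 given partner state s2-1
        .unit_twostate(p, x, shift = eps2 * m[s2, 2], n_grid = n_grid))
      U2 <- lapply(1:2, function(s1)
        .unit_twostate(p, x, shift = eps1 * m[s1, 1], n_grid = n_grid))
      upd <- function(U) {
        mm <- rowMeans(vapply(U, function(u) u$means, numeric(2)),
                       na.rm = TRUE)
        mm[!is.finite(mm)] <- c(0.0103, 2.02)[!is.finite(mm)]
        mm
      }
      m <- cbind(upd(U1), upd(U2))
    }
    lograte <- function(u, dir) {           # dir 1: off->on, 2: on->off
      if (u$mono) {
        if ((dir == 1) == u$on) fast else -Inf
      } else log(if (dir == 1) u$r01 else u$r10)
    }
    lr <- c(r1_on_s20  = lograte(U1[[1]], 1), r1_on_s21  = lograte(U1[[2]], 1),
            r2_on_s10  = lograte(U2[[1]], 1), r2_on_s11  = lograte(U2[[2]], 1),
            r1_off_s20 = lograte(U1[[1]], 2), r1_off_s21 = lograte(U1[[2]], 2),
            r2_off_s10 = lograte(U2[[1]], 2), r2_off_s11 = lograte(U2[[2]], 2))
    pi <- .pair_tree_stationary(lr)
    # conditional within-well sampling tables: cdf per (unit, partner state,
    # own state)
    welltab <- function(u, s) {             # s: 1 OFF, 2 ON
      idx <- if (s == 1) seq_len(u$split) else u$split:length(u$grid)
      ww <- u$w[idx]
      if (sum(ww) <= 0) return(NULL)
      list(y = u$grid[idx], cdf = cumsum(ww) / sum(ww))
    }
    list(x = x, pi = pi,
         tabs = list(u1 = lapply(1:2, function(s2)
                       lapply(1:2, function(s1) welltab(U1[[s2]], s1))),
                     u2 = lapply(1:2, function(s1)
                       lapply(1:2, function(s2) welltab(U2[[s1]], s2)))))
  })
}

# Draw (y1, y2) pairs from a precomputed cross-talk channel; x snapped to
# the nearest channel grid point in log space.
.crosstalk_sample <- function(channel, x) {
  xg <- vapply(channel, `[[`, numeric(1), "x")
  n <- length(x)
  ix <- vapply(log(x), function(l) which.min(abs(log(xg) - l)), integer(1))
  y1 <- y2 <- numeric(n)
  us <- stats::runif(3 * n)
  for (i in seq_len(n)) {
    ch <- channel[[ix[i]]]
    st <- findInterval(us[i], cumsum(ch$pi)) + 1L   # 1..4
    s1 <- c(1L, 2L, 1L, 2L)[st]; s2 <- c(1L, 1L, 2L, 2L)[st]
    t1 <- ch$tabs$u1[[s2]][[s1]]
    t2 <- ch$tabs$u2[[s1]][[s2]]
    y1[i] <- if (is.null(t1)) NA_real_ else
      t1$y[findInterval(us[n + i], t1$cdf) + 1L]
    y2[i] <- if (is.null(t2)) NA_real_ else
      t2$y[findInterval(us[2 * n + i], t2$cdf) + 1L]
  }
  cbind(y1, y2)
}
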