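#' Signal waveforms
#'
#' The signal is either a step of fixed amplitude switched on at `t = 0`
#' (simple and bistable units) or a pulse of one unit of normalized time
#' (excitable unit).
#'
#' @param kind `"step"` or `"pulse"`.
#' @param amplitude signal level `x >= 0`.
#' @param pulse_duration pulse length in normalized time (pulse only).
#' @return a `signal_waveform` object.
#' @export
signal_waveform <- function(kind = c("step", "pulse"), amplitude,
                            pulse_duration = 1) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (pulse_duration <= 0) stop("`pulse_duration` must be > 0")
  structure(list(kind = kind, amplitude = amplitude,
                 pulse_duration = pulse_duration),
            class = "signal_waveform")
}

.waveform_value <- function(w, t) {
  if (w$kind == "step") rep(w$amplitude, length(t))
  else ifelse(t <= w$pulse_duration, w$amplitude, 0)
}

#' Integration settings for the Langevin engine
#'
#' Euler-Maruyama settings. The defaults (`dt = 0.01`, `t_max = 50`) suit
#' the 1-D units whose relaxation times are O(1) in the rescaled model; the
#' excitable unit uses a much longer horizon (`t_max = 151`) because its
#' excursion evolves on slow O(10-100) timescales.
#'
#' @param dt time step.
#' @param t_max integration horizon.
#' @param seed optional integer seed.
#' @param boundary negative-state policy; only `"clip"` (project to 0) is
#'   implemented.
#' @return an `integration_config` object.
#' @export
integration_config <- function(dt = 0.01, t_max = 50, seed = NULL,
                               boundary = "clip") {
  if (dt <= 0 || t_max <= dt) stop("need dt > 0 and t_max > dt")
  boundary <- match.arg(boundary, "clip")
  structure(list(dt = dt, t_max = t_max, seed = seed, boundary = boundary),
            class = "integration_config")
}

# cached deterministic rest state of a unit at x = 0
.rest_state_cache <- new.env(parent = emptyenv())

.rest_state <- function(p) {
  key <- paste(unlist(unit_params_to_list(p)), collapse = "_")
  if (!is.null(.rest_state_cache[[key]])) return(.rest_state_cache[[key]])
  fp <- deterministic_fixed_points(p = p, x = 0)
  st <- fp[fp$stable, , drop = FALSE]
  if (nrow(st) == 0) stop("no stable rest state at x = 0")
  out <- as.numeric(st[1, setdiff(names(st), "stable")])
  .rest_state_cache[[key]] <- out
  out
}

#' Integrate a single unit under a signal waveform
#'
#' Euler-Maruyama integration of one threshold unit with multiplicative
#' intrinsic noise, starting from its deterministic steady state at
#' `x = 0`. Negative excursions are clipped to zero, the standard
#' chemical-Langevin regularization.
#'
#' @param kind unit kind (taken from `p` when `NULL`).
#' @param p a `unit_params` object.
#' @param waveform a [signal_waveform()].
#' @param cfg an [integration_config()].
#' @param extrinsic_offset constant production-rate offset shared by all
#'   units of a cell (one extrinsic-noise draw), default 0.
#' @param init `"baseline"` starts from the deterministic rest state;
#'   `"stationary"` (1-D units) starts from a draw of the stationary
#'   Fokker-Planck density at the waveform amplitude, useful for
#'   stationarity checks.
#' @return a `trajectory` object: list with `times`, `states` (matrix with
#'   column `y`, plus `z` for the excitable unit), `params`, `waveform`.
#' @examples
#' tr <- integrate_unit(p = bistable_unit_params(K = 1e12),
#'                      waveform = signal_waveform("step", 0.005),
#'                      cfg = integration_config(seed = 1))
#' utils::tail(tr$states[, "y"], 1)
#' @export
integrate_unit <- function(kind = NULL, p, waveform, cfg = integration_config(),
                           extrinsic_offset = 0,
                           init = c("baseline", "stationary")) {
  if (is.null(kind)) kind <- p$kind
  init <- match.arg(init)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nsteps <- round(cfg$t_max / cfg$dt)
  times <- seq(0, by = cfg$dt, length.out = nsteps + 1)
  sdt <- sqrt(cfg$dt)
  if (kind %in% c("simple", "bistable")) {
    y <- numeric(nsteps + 1)
    y[1] <- if (init == "stationary") {
      d <- stationary_density_fp(kind, p, x = waveform$amplitude)
      sample(d$y, 1, prob = d$density)
    } else .rest_state(p)[1]
    xv <- .waveform_value(waveform, times)
    for (s in seq_len(nsteps)) {
      dd <- if (kind == "simple")
        simple_drift_diffusion(y[s], xv[s], p)
      else bistable_drift_diffusion(y[s], xv[s], p)
      yn <- y[s] + (dd$drift + extrinsic_offset) * cfg$dt +
        dd$q * sdt * stats::rnorm(1)
      if (!is.finite(yn))
        stop("integration diverged at dt = ", cfg$dt)
      y[s + 1] <- max(yn, 0)
    }
    states <- cbind(y = y)
  } else if (kind == "excitable") {
    st <- matrix(0, nsteps + 1, 2, dimnames = list(NULL, c("y", "z")))
    st[1, ] <- if (init == "stationary")
      stop("stationary init is only available for 1-D units")
    else .rest_state(p)
    xv <- .waveform_value(waveform, times)
    q <- sqrt((p$beta + 1) / p$K)
    for (s in seq_len(nsteps)) {
      dd <- excitable_drift_diffusion(st[s, ], xv[s], p)
      yn <- st[s, 1] + dd$drift[1, "dy"] * cfg$dt
      zn <- st[s, 2] + (dd$drift[1, "dz"] + extrinsic_offset) * cfg$dt +
        q * sdt * stats::rnorm(1)
      if (!is.finite(yn) || !is.finite(zn))
        stop("integration diverged at dt = ", cfg$dt)
      st[s + 1, ] <- pmax(c(yn, zn), 0)
    }
    states <- st
  } else stop("unknown kind: ", kind)
  structure(list(times = times, states = states, params = p,
                 waveform = waveform, cfg = cfg),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s unit, %d steps, t in [0, %g]\n",
              x$params$kind, length(x$times) - 1, max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states)
}

#' Write a trajectory to a tidy CSV file
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Steady-state response of a trajectory
#'
#' `Delta y = y(x) - y(x = 0)`: the time average of `y` over the final
#' stationarity window minus the baseline rest expression. A linear trend
#' in the window larger than `trend_tol` times the response scale flags the
#' result as non-stationary (attribute `stationary`).
#'
#' @param traj a `trajectory` from [integrate_unit()].
#' @param baseline rest expression at `x = 0`; defaults to the trajectory's
#'   initial state.
#' @param window fraction of the horizon used as stationarity window
#'   (default last 20%).
#' @param trend_tol relative trend tolerance for the stationarity check.
#' @return the response `Delta y` with attribute `stationary`.
#' @export
response_delta <- function(traj, baseline = NULL, window = 0.2,
                           trend_tol = 0.05) {
  y <- traj$states[, 1]
  n <- length(y)
  if (is.null(baseline)) baseline <- y[1]
  iw <- seq.int(max(1L, n - floor(window * n)), n)
  m <- mean(y[iw])
  tt <- traj$times[iw]
  slope <- stats::coef(stats::lm.fit(cbind(1, tt), y[iw]))[2]
  drift_span <- abs(slope) * (max(tt) - min(tt))
  scale <- max(abs(m - baseline), 0.05)
  out <- m - baseline
  attr(out, "stationary") <- drift_span <= trend_tol * scale
  if (!attr(out, "stationary"))
    warning("trajectory still trending in the stationarity window")
  out
}

# cached excitation threshold: midpoint between the rest expression and the
# deterministic excursion peak for a strong (x = 9) calibration pulse
.exc_threshold_cache <- new.env(parent = emptyenv())

#' Excitation threshold of the excitable unit
#'
#' The Boolean excitation classifier needs a cut on the post-pulse maximum
#' of `y`. It is calibrated once per parameter set as the midpoint between
#' the rest expression and the deterministic excursion peak elicited by a
#' strong calibration pulse (amplitude 9, ten times the excitation
#' threshold scale).
#'
#' @param p excitable `unit_params`.
#' @param calibration_x amplitude of the deterministic calibration pulse.
#' @return the threshold on `max y`.
#' @export
excitation_threshold <- function(p = excitable_unit_params(),
                                 calibration_x = 9) {
  key <- paste(c(unlist(unit_params_to_list(p)), calibration_x),
               collapse = "_")
  if (!is.null(.exc_threshold_cache[[key]]))
    return(.exc_threshold_cache[[key]])
  rest <- .rest_state(p)
  det <- .em_ensemble_excitable(calibration_x, 1L, p$alpha0, p$alpha, p$beta,
                                p$sigma, p$n, p$m, 1e18, 0.01, 15100L, 100L,
                                rest[1], rest[2])
  peak <- det$ymax[1, 1]
  if (peak < 2 * rest[1])
    stop("calibration pulse did not excite the unit; raise `calibration_x`")
  out <- (rest[1] + peak) / 2
  .exc_threshold_cache[[key]] <- out
  out
}

#' Boolean excitation classifier
#'
#' `1` if the post-pulse maximum of `y` exceeds the calibrated excursion
#' threshold ([excitation_threshold()]), else `0`.
#'
#' @param traj a `trajectory` of an excitable unit.
#' @param p the unit's parameters (defaults to the trajectory's).
#' @param threshold override for the excursion cut.
#' @return integer 0/1.
#' @export
classify_excitation <- function(traj, p = NULL, threshold = NULL) {
  if (is.null(p)) p <- traj$params
  if (is.null(threshold)) threshold <- excitation_threshold(p)
  post <- traj$times > traj$waveform$pulse_duration
  as.integer(max(traj$states[post, "y"]) > threshold)
}

#' Binary readout of the bistable unit
#'
#' OFF (`0`) if `y < 1`, ON (`1`) otherwise.
#'
#' @param y expression level(s).
#' @return integer 0/1 vector.
#' @export
binarize_bistable <- function(y) as.integer(y >= 1)
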