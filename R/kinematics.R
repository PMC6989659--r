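#' @name kinematics
#' @title From LED tracking to position, speed and head direction
#'
#' @description
#' The kinematic stage converts raw two-LED video tracking (30 Hz, missing
#' samples allowed) into smoothed position, instantaneous running speed and
#' head direction on the common 25.6-ms grid. Running speed drives every
#' downstream speed statistic; its validity mask (tracking valid and speed
#' within the walking band, by default 2-50 cm/s) is the mask used by the
#' speed score, slope, information and temporal-shift analyses.
NULL

#' Interpolate tracked position onto the analysis grid
#'
#' Linearly interpolates the front-LED position into uniform bins. Missing
#' video samples are bridged by the interpolation; bins falling inside a
#' tracking gap longer than `max_gap` are marked invalid.
#'
#' @param traj a trajectory data frame as produced by [simulate_trajectory()]
#'   or [read_session()]: columns `t`, `fx`, `fy`, `rx`, `ry` (cm, `NA` when
#'   the sample is missing).
#' @param dt bin width in seconds (default 0.0256).
#' @param duration session duration in seconds; defaults to the last
#'   timestamp.
#' @param max_gap longest tracking gap (s) bridged without masking
#'   (default 1).
#' @param led which LED to interpolate, `"front"` (the animal's position) or
#'   `"rear"`.
#' @return list with `binned_series` components `x` and `y`.
#' @export
interpolate_position <- function(traj, dt = 0.0256, duration = NULL,
                                 max_gap = 1, led = c("front", "rear")) {
  led <- match.arg(led)
  cx <- if (led == "front") "fx" else "rx"
  cy <- if (led == "front") "fy" else "ry"
  ok <- is.finite(traj[[cx]]) & is.finite(traj[[cy]])
  if (sum(ok) < 2L) stop("fewer than 2 valid tracking samples")
  tt <- traj$t[ok]
  duration <- duration %||% max(traj$t)
  n <- as.integer(floor(duration / dt))
  tb <- (seq_len(n) - 0.5) * dt
  xi <- stats::approx(tt, traj[[cx]][ok], xout = tb, rule = 2)$y
  yi <- stats::approx(tt, traj[[cy]][ok], xout = tb, rule = 2)$y
  # mask bins inside long gaps between consecutive valid samples
  valid <- rep(TRUE, n)
  gaps <- diff(tt)
  long <- which(gaps > max_gap)
  for (g in long)
    valid[tb > tt[g] & tb < tt[g + 1L]] <- FALSE
  # extrapolated edges follow the same gap rule
  valid[tb < tt[1L] - max_gap | tb > tt[length(tt)] + max_gap] <- FALSE
  list(x = binned_series(xi, dt = dt, valid = valid),
       y = binned_series(yi, dt = dt, valid = valid))
}

# tricube weights over integer offsets -h..h (interior window)
tricube_weights <- function(h) {
  d <- abs(seq(-h, h))
  (1 - (d / max(d, 1))^3)^3
}

#' Locally weighted linear smoothing of a position series
#'
#' Local regression with tricube-weighted linear least squares and a
#' first-degree polynomial over a centred window (default 11 bins, i.e.
#' 281.6 ms at the 25.6-ms grid). For the symmetric interior window the
#' first-degree fit at the centre reduces to a fixed FIR weighted mean;
#' the first and last half-windows are solved as truncated weighted
#' least-squares fits. A linear ramp passes through unchanged.
#'
#' @param series a `binned_series`.
#' @param width window width in seconds (default 0.2816); must span an odd
#'   number of bins.
#' @return a `binned_series` of smoothed values (mask preserved).
#' @export
smooth_position <- function(series, width = 0.2816) {
  stopifnot(inherits(series, "binned_series"))
  w <- as.integer(round(width / series$dt))
  if (w %% 2L == 0L) stop("window width must be an odd number of bins")
  h <- w %/% 2L
  y <- series$values
  n <- length(y)
  if (n < w) {
    warning("series shorter than smoothing window; returned unsmoothed")
    return(series)
  }
  tw <- tricube_weights(h)
  out <- conv_same(y, tw / sum(tw))
  # truncated endpoint windows: weighted first-degree fit evaluated at the
  # target bin, window clipped to the series
  for (i in c(seq_len(h), (n - h + 1L):n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    d <- (lo:hi) - i
    ww <- (1 - (abs(d) / max(abs(d)))^3)^3
    X <- cbind(1, d)
    fit <- stats::lm.wfit(X, y[lo:hi], ww)
    out[i] <- fit$coefficients[1L]
  }
  binned_series(out, dt = series$dt, t0 = series$t0, valid = series$valid)
}

#' Instantaneous running speed
#'
#' Per-bin Euclidean displacement of the smoothed position divided by the
#' bin width, then Gaussian-smoothed (default SD 512 ms, kernel truncated at
#' +/- 4 SD with edge renormalisation). The validity mask keeps bins where
#' tracking is valid and the smoothed speed lies inside `[vmin, vmax]`
#' (inclusive), the walking band used by all speed statistics.
#'
#' @param x,y smoothed position `binned_series` (cm), aligned.
#' @param sd Gaussian smoothing SD in seconds (default 0.512; the filter-size
#'   sensitivity analyses use 0.128, 0.256 and 1.024).
#' @param vmin,vmax walking-band bounds in cm/s (defaults 2 and 50).
#' @return a `binned_series` of speed in cm/s with the walking-band mask.
#' @export
compute_speed <- function(x, y, sd = 0.512, vmin = 2, vmax = 50) {
  check_aligned(x, y)
  n <- length(x$values)
  dx <- diff(x$values); dy <- diff(y$values)
  d <- sqrt(dx^2 + dy^2) / x$dt             # speed over each bin-to-bin step
  # centre each bin's speed on the bin: average of the steps either side
  v <- c(d[1L], (d[-1L] + d[-(n - 1L)]) / 2, d[n - 1L])
  valid <- x$valid & y$valid
  sm <- gaussian_smooth(binned_series(v, dt = x$dt, t0 = x$t0, valid = valid),
                        sd = sd)
  mask <- sm$valid & sm$values >= vmin & sm$values <= vmax
  binned_series(sm$values, dt = x$dt, t0 = x$t0, valid = mask)
}

#' Head direction from the two tracking LEDs
#'
#' The direction of the front LED relative to the rear LED, `atan2` per bin,
#' mapped to `[0, 2*pi)`. Bins where either LED is missing are invalid.
#'
#' @inheritParams interpolate_position
#' @return a `binned_series` of head direction in radians.
#' @export
head_direction <- function(traj, dt = 0.0256, duration = NULL, max_gap = 1) {
  if (all(!is.finite(traj$rx)))
    stop("rear LED absent for the whole session; directional analyses disabled")
  f <- interpolate_position(traj, dt = dt, duration = duration,
                            max_gap = max_gap, led = "front")
  r <- interpolate_position(traj, dt = dt, duration = duration,
                            max_gap = max_gap, led = "rear")
  ang <- atan2(f$y$values - r$y$values, f$x$values - r$x$values) %% (2 * pi)
  binned_series(ang, dt = dt, valid = f$x$valid & r$x$valid)
}
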