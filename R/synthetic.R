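#' @name synthetic_session
#' @title Synthetic sessions with known ground truth
#'
#' @description
#' Generates complete recording sessions whose statistical structure mirrors
#' an open-field foraging experiment: a bounded two-LED trajectory with
#' realistic speed dynamics (a reflected Ornstein-Uhlenbeck speed process
#' spending ~90% of its time between 2 and 50 cm/s), an ~8 Hz theta LFP at
#' 1250 Hz, and spike trains drawn as inhomogeneous point processes with a
#' linear speed gain at a controllable temporal lag, von Mises theta-phase
#' modulation, optional place/grid/head-direction tuning, and controllable
#' burst/refractory structure. The true parameters are recorded verbatim so
#' every analysis stage has a parameter-recovery oracle.
NULL

#' Ground-truth parameters of one synthetic unit
#'
#' @param baseline_rate baseline firing rate, Hz (>= 0).
#' @param speed_gain linear speed gain b, Hz per cm/s.
#' @param speed_lag temporal lag of the speed drive, seconds; positive
#'   means the rate leads (predicts) speed, i.e. prospective coding.
#' @param theta_kappa von Mises concentration of theta-phase modulation
#'   (0 = none).
#' @param theta_pref_phase preferred theta phase, radians (peak = 0).
#' @param place optional place field, `list(cx, cy, width, gain)` (cm,
#'   Gaussian SD, peak multiplier).
#' @param grid optional grid tuning, `list(spacing, orientation, gain)`
#'   (cm, radians, multiplier); an imposed three-cosine rate map.
#' @param head_dir optional head-direction tuning, `list(mu, kappa)`.
#' @param burst_prob probability that a spike is followed by a burst
#'   partner (default 0).
#' @param burst_isi intra-burst interval, seconds (default 0.004).
#' @param refractory absolute refractory period, seconds (default 0.002).
#' @return a list of class `unit_truth`.
#' @export
unit_truth <- function(baseline_rate = 5, speed_gain = 0, speed_lag = 0,
                       theta_kappa = 0, theta_pref_phase = 0,
                       place = NULL, grid = NULL, head_dir = NULL,
                       burst_prob = 0, burst_isi = 0.004,
                       refractory = 0.002) {
  stopifnot(baseline_rate >= 0, refractory > 0, burst_prob >= 0,
            burst_prob <= 1)
  structure(list(baseline_rate = baseline_rate, speed_gain = speed_gain,
                 speed_lag = speed_lag, theta_kappa = theta_kappa,
                 theta_pref_phase = theta_pref_phase, place = place,
                 grid = grid, head_dir = head_dir, burst_prob = burst_prob,
                 burst_isi = burst_isi, refractory = refractory),
            class = "unit_truth")
}

#' Simulate an open-field trajectory
#'
#' Speed follows an Ornstein-Uhlenbeck process reflected at zero (mean 15
#' cm/s, relaxation 0.5 /s, diffusion chosen so ~90% of time falls in the
#' 2-50 cm/s walking band); heading is a smoothed random walk reflected at
#' the arena walls. The rear LED trails the front LED by `led_sep` cm along
#' the heading, emulating midline-mounted tracking LEDs 10-15 cm apart.
#'
#' @param duration session length, seconds (>= 60; shorter sessions leave no
#'   room for the 30-s circular-shuffle margin downstream).
#' @param arena_side arena side length, cm (120 or 180 in the emulated
#'   experiments; any positive value accepted).
#' @param seed integer RNG seed.
#' @param fps video frame rate, Hz (default 30).
#' @param speed_mean,speed_theta,speed_sigma OU parameters of the speed
#'   process (cm/s, 1/s, cm/s/sqrt(s)).
#' @param heading_sigma heading random-walk SD, rad/sqrt(s).
#' @param led_sep LED separation, cm (default 12).
#' @param script optional deterministic script: a function `(t) ->
#'   c(x, y, heading)` overriding the stochastic model (used by tests).
#' @return data frame of class `trajectory` with columns `t`, `fx`, `fy`,
#'   `rx`, `ry` (cm; `NA` marks missing samples -- none are generated here,
#'   dropouts can be injected afterwards).
#' @export
simulate_trajectory <- function(duration, arena_side = 120, seed = 1,
                                fps = 30, speed_mean = 15, speed_theta = 0.5,
                                speed_sigma = 8, heading_sigma = 1.2,
                                led_sep = 12, script = NULL) {
  if (duration < 60) stop("duration must be >= 60 s (shuffle margin)")
  dt <- 1 / fps
  t <- seq(0, duration, by = dt)
  n <- length(t)
  if (!is.null(script)) {
    sc <- t(vapply(t, script, numeric(3)))
    x <- sc[, 1]; y <- sc[, 2]; hd <- sc[, 3]
  } else {
    set.seed(seed)
    v <- numeric(n); hd <- numeric(n); x <- numeric(n); y <- numeric(n)
    v[1] <- max(0, stats::rnorm(1, speed_mean, speed_sigma / sqrt(2 * speed_theta)))
    hd[1] <- stats::runif(1, 0, 2 * pi)
    x[1] <- stats::runif(1, 0.2, 0.8) * arena_side
    y[1] <- stats::runif(1, 0.2, 0.8) * arena_side
    dv <- stats::rnorm(n - 1, 0, speed_sigma * sqrt(dt))
    dh <- stats::rnorm(n - 1, 0, heading_sigma * sqrt(dt))
    margin <- 2
    for (i in 2:n) {
      v[i] <- abs(v[i - 1] + speed_theta * (speed_mean - v[i - 1]) * dt + dv[i - 1])
      hd[i] <- hd[i - 1] + dh[i - 1]
      x[i] <- x[i - 1] + v[i] * cos(hd[i]) * dt
      y[i] <- y[i - 1] + v[i] * sin(hd[i]) * dt
      # reflect at walls, flipping the offending heading component
      if (x[i] < margin || x[i] > arena_side - margin) {
        x[i] <- min(max(x[i], margin), arena_side - margin)
        hd[i] <- pi - hd[i]
      }
      if (y[i] < margin || y[i] > arena_side - margin) {
        y[i] <- min(max(y[i], margin), arena_side - margin)
        hd[i] <- -hd[i]
      }
      hd[i] <- hd[i] %% (2 * pi)
    }
  }
  out <- data.frame(t = t, fx = x, fy = y,
                    rx = x - led_sep * cos(hd), ry = y - led_sep * sin(hd))
  attr(out, "arena_side") <- arena_side
  attr(out, "heading") <- hd
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Simulate a theta-band LFP channel
#'
#' A sinusoid at `f0` Hz (optionally with speed-modulated instantaneous
#' frequency) plus broadband Gaussian noise, sampled at 1250 Hz. Signal
#' peaks are positive maxima, so their Hilbert phase is 0 under the phase
#' convention used throughout.
#'
#' @param duration seconds.
#' @param f0 carrier frequency, Hz (theta band, 5-11).
#' @param speed_fm optional frequency modulation, Hz per cm/s, applied to a
#'   supplied `speed` series.
#' @param speed optional speed `binned_series` (needed when `speed_fm` is
#'   set).
#' @param noise_sd broadband noise SD relative to unit carrier amplitude.
#' @param rate sampling rate, Hz (default 1250).
#' @param seed integer RNG seed.
#' @param region_layer channel label (default `"EC3"`).
#' @return list with `samples`, `rate`, `region_layer` and attribute
#'   `true_phase` (the unwrapped carrier phase, radians).
#' @export
simulate_theta_lfp <- function(duration, f0 = 8, speed_fm = NULL,
                               speed = NULL, noise_sd = 0.1, rate = 1250,
                               seed = 1, region_layer = "EC3") {
  stopifnot(f0 >= 5, f0 <= 11)
  set.seed(seed)
  n <- as.integer(round(duration * rate))
  tt <- (seq_len(n) - 1) / rate
  f_inst <- rep(f0, n)
  if (!is.null(speed_fm) && !is.null(speed)) {
    v <- stats::approx(bin_times(speed), speed$values, xout = tt, rule = 2)$y
    f_inst <- f0 + speed_fm * (v - mean(v))
  }
  phase <- 2 * pi * cumsum(f_inst) / rate
  samples <- cos(phase) + stats::rnorm(n, 0, noise_sd)
  out <- list(samples = samples, rate = rate, region_layer = region_layer)
  attr(out, "true_phase") <- phase
  out
}

# per-unit spatial gain field evaluated at positions (vectorised)
spatial_gain <- function(truth, x, y) {
  g <- rep(1, length(x))
  if (!is.null(truth$place)) {
    p <- truth$place
    g <- g * (1 + (p$gain - 1) *
                exp(-((x - p$cx)^2 + (y - p$cy)^2) / (2 * p$width^2)))
  }
  if (!is.null(truth$grid)) {
    gr <- truth$grid
    k <- 4 * pi / (sqrt(3) * gr$spacing)
    ang <- gr$orientation + c(0, pi / 3, 2 * pi / 3)
    s <- Reduce(`+`, lapply(ang, function(a)
      cos(k * (x * cos(a) + y * sin(a)))))
    g <- g * (1 + (gr$gain - 1) * (s + 1.5) / 4.5)
  }
  g
}

#' Simulate one spike train from ground truth
#'
#' The driving intensity is
#' `lambda(t) = max(0, baseline + b * v(t + lag)) * g_theta(phi(t)) * g_space(x(t))`
#' evaluated on a 1-ms grid, where `g_theta` is a von Mises gain normalised
#' to unit mean and `g_space` the optional place/grid/head-direction gain.
#' Spikes are drawn by exact thinning of a homogeneous Poisson process at
#' the grid maximum; optional burst partners are appended with probability
#' `burst_prob` at `burst_isi`, and the absolute refractory period is
#' enforced last.
#'
#' @param truth a [unit_truth()].
#' @param traj a `trajectory` data frame.
#' @param theta_phase_fun optional function `(t) -> unwrapped phase` for the
#'   theta drive; default is an 8 Hz clock.
#' @param duration seconds; defaults to the trajectory length.
#' @param seed integer RNG seed.
#' @param res intensity grid resolution, seconds (default 0.001).
#' @return sorted numeric vector of spike times with attribute `truth`.
#' @export
simulate_unit <- function(truth, traj, theta_phase_fun = NULL,
                          duration = NULL, seed = 1, res = 0.001) {
  stopifnot(inherits(truth, "unit_truth"))
  duration <- duration %||% max(traj$t)
  set.seed(seed)
  tg <- seq(0, duration - res, by = res) + res / 2
  x <- stats::approx(traj$t, traj$fx, xout = tg, rule = 2)$y
  y <- stats::approx(traj$t, traj$fy, xout = tg, rule = 2)$y
  # frame-to-frame speed, attributed to the midpoint of each frame interval
  vraw <- sqrt(diff(traj$fx)^2 + diff(traj$fy)^2) / diff(traj$t)
  tmid <- (traj$t[-1] + traj$t[-nrow(traj)]) / 2
  v <- stats::approx(tmid, vraw, xout = tg + truth$speed_lag, rule = 2)$y
  lam <- pmax(0, truth$baseline_rate + truth$speed_gain * v)
  if (truth$theta_kappa > 0) {
    ph <- if (is.null(theta_phase_fun)) 2 * pi * 8 * tg else theta_phase_fun(tg)
    lam <- lam * exp(truth$theta_kappa * cos(ph - truth$theta_pref_phase)) /
      besselI(truth$theta_kappa, 0)
  }
  if (!is.null(truth$head_dir)) {
    hd <- attr(traj, "heading")
    if (!is.null(hd)) {
      hdi <- stats::approx(traj$t, hd, xout = tg, rule = 2)$y
      lam <- lam * exp(truth$head_dir$kappa * cos(hdi - truth$head_dir$mu)) /
        besselI(truth$head_dir$kappa, 0)
    }
  }
  lam <- lam * spatial_gain(truth, x, y)
  lam_max <- max(lam)
  if (lam_max > 1 / truth$refractory)
    warning("peak intensity exceeds 1/refractory; requested rate unattainable")
  if (lam_max <= 0) {
    st <- numeric(0)
  } else {
    n_cand <- stats::rpois(1, lam_max * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    gi <- pmin(length(lam), pmax(1L, as.integer(ceiling(cand / res))))
    st <- cand[stats::runif(n_cand) < lam[gi] / lam_max]
  }
  if (truth$burst_prob > 0 && length(st) > 0) {
    partner <- st[stats::runif(length(st)) < truth$burst_prob] + truth$burst_isi
    st <- sort(c(st, partner[partner < duration]))
  }
  # absolute refractory period
  if (length(st) > 1) {
    keep <- logical(length(st)); keep[1] <- TRUE; last <- st[1]
    for (i in 2:length(st)) {
      if (st[i] - last >= truth$refractory) { keep[i] <- TRUE; last <- st[i] }
    }
    st <- st[keep]
  }
  attr(st, "truth") <- truth
  st
}

#' Simulate a complete session
#'
#' Trajectory, theta LFP and one spike train per supplied ground-truth
#' record, assembled into a session bundle. Each unit draws from its own
#' RNG stream derived from `(seed, unit index)`, so adding units never
#' perturbs existing ones.
#'
#' @param truths list of [unit_truth()] records.
#' @param duration seconds (default 1200).
#' @param arena_side cm (default 120).
#' @param seed master integer seed.
#' @param lfp_noise_sd theta LFP noise SD (default 0.1).
#' @param region_layers character vector recycled over units (default
#'   `"CA1"`).
#' @return a `session_bundle` (see [session_bundle()]) whose `units` carry
#'   `truth` attributes and which has a `ground_truth` data frame attached.
#' @export
simulate_session <- function(truths, duration = 1200, arena_side = 120,
                             seed = 1, lfp_noise_sd = 0.1,
                             region_layers = "CA1") {
  traj <- simulate_trajectory(duration, arena_side = arena_side,
                              seed = unit_seed(seed, 0))
  lfp <- simulate_theta_lfp(duration, noise_sd = lfp_noise_sd,
                            seed = unit_seed(seed, 1e6))
  phase_fun <- local({
    tp <- attr(lfp, "true_phase"); fs <- lfp$rate
    function(t) stats::approx((seq_along(tp) - 1) / fs, tp, xout = t,
                              rule = 2)$y
  })
  region_layers <- rep_len(region_layers, length(truths))
  units <- lapply(seq_along(truths), function(i) {
    st <- simulate_unit(truths[[i]], traj, theta_phase_fun = phase_fun,
                        duration = duration, seed = unit_seed(seed, i))
    list(unit_id = sprintf("u%03d", i), spike_times = as.numeric(st),
         region_layer = region_layers[i], shank = 1L + (i - 1L) %/% 8L,
         truth = truths[[i]])
  })
  gt <- do.call(rbind, lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    data.frame(unit_id = sprintf("u%03d", i),
               baseline_rate = tr$baseline_rate, speed_gain = tr$speed_gain,
               speed_lag = tr$speed_lag, theta_kappa = tr$theta_kappa,
               theta_pref_phase = tr$theta_pref_phase,
               burst_prob = tr$burst_prob, refractory = tr$refractory)
  }))
  ses <- session_bundle(session_id = sprintf("synthetic-%d", seed),
                        arena_side = arena_side, trajectory = traj,
                        lfp = list(EC3 = lfp), units = units,
                        duration = duration)
  attr(ses, "ground_truth") <- gt
  ses
}
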