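#' @name theta_analysis
#' @title Theta epochs, spike phases and theta modulation
#'
#' @description
#' Theta (5-11 Hz) epochs are detected from the band-power ratio of a
#' reference LFP channel; spike theta phases come from the Hilbert transform
#' of the band-pass-filtered trace, with the convention that positive LFP
#' peaks are phase 0 (and 2*pi) and troughs are pi. Circular first-moment
#' statistics give each unit its preferred phase and resultant length, and
#' the theta index quantifies ~8 Hz periodicity of the spike
#' autocorrelogram.
NULL

window_band_power <- function(seg, fs, band) {
  n <- length(seg)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))   # Hann taper
  X <- stats::fft(seg * w)
  f <- (seq_len(n) - 1) * fs / n
  p <- Mod(X)^2
  sum(p[f >= band[1] & f <= band[2]])
}

#' Detect theta epochs from an LFP channel
#'
#' Sliding-window spectral estimate; a window belongs to a theta epoch when
#' the ratio of 5-11 Hz power to the power of the flanking bands (1-4 Hz and
#' 12-14 Hz) exceeds `ratio_thresh`. Adjacent qualifying windows are merged
#' and epochs shorter than `min_dur` are dropped.
#'
#' @param lfp list with `samples` (numeric) and `rate` (Hz), as stored in a
#'   session bundle.
#' @param win,step sliding-window length and step, seconds (defaults 2, 1).
#' @param ratio_thresh theta/flank power ratio threshold (default 2).
#' @param min_dur minimum epoch duration, seconds (default 1).
#' @param theta_band,flank_low,flank_high frequency bands, Hz.
#' @return matrix with columns `start`, `end` (seconds), non-overlapping and
#'   sorted; zero rows when no theta is present.
#' @export
detect_theta_epochs <- function(lfp, win = 2, step = 1, ratio_thresh = 2,
                                min_dur = 1, theta_band = c(5, 11),
                                flank_low = c(1, 4), flank_high = c(12, 14)) {
  fs <- lfp$rate
  x <- as.numeric(lfp$samples)
  nw <- as.integer(round(win * fs))
  ns <- as.integer(round(step * fs))
  if (length(x) < nw) stop("LFP shorter than one analysis window")
  if (all(x == 0)) {
    warning("all-zero LFP; no theta epochs")
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  starts <- seq(1L, length(x) - nw + 1L, by = ns)
  hit <- vapply(starts, function(s) {
    seg <- x[s:(s + nw - 1L)]
    th <- window_band_power(seg, fs, theta_band)
    fl <- window_band_power(seg, fs, flank_low) +
      window_band_power(seg, fs, flank_high)
    fl > 0 && th / fl > ratio_thresh
  }, logical(1))
  if (!any(hit))
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  t_start <- (starts - 1L) / fs
  t_end <- t_start + win
  # merge overlapping/adjacent qualifying windows
  runs <- rle(hit)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  ep <- cbind(start = t_start[idx_start[runs$values]],
              end = t_end[idx_end[runs$values]])
  ep <- ep[ep[, 2] - ep[, 1] >= min_dur, , drop = FALSE]
  ep
}

#' Instantaneous theta phase of an LFP channel
#'
#' Zero-phase (forward-backward) Butterworth band-pass, then the analytic
#' signal. The returned phase is unwrapped (monotonically increasing up to
#' noise); take it modulo `2*pi` for wrapped phases. By construction a
#' positive peak of the filtered trace has wrapped phase 0 and a trough pi.
#'
#' @inheritParams detect_theta_epochs
#' @param band band-pass edges in Hz (default `c(5, 11)`).
#' @param order Butterworth order (default 3).
#' @return numeric vector of unwrapped phase, one value per LFP sample.
#' @export
theta_phase <- function(lfp, band = c(5, 11), order = 3) {
  fs <- lfp$rate
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, as.numeric(lfp$samples))
  ph <- Arg(analytic_signal(filt))
  as.numeric(signal::unwrap(ph))
}

#' Theta phase of each spike
#'
#' Spikes are kept only when they fall inside a detected theta epoch and,
#' when a speed series is supplied, inside the walking-speed mask. Each
#' retained spike's phase is linearly interpolated from the unwrapped LFP
#' phase and wrapped into `[0, 2*pi)`.
#'
#' @param lfp LFP channel (list with `samples`, `rate`).
#' @param epochs theta-epoch matrix from [detect_theta_epochs()], or `NULL`
#'   to use the whole session.
#' @param spike_times numeric vector, seconds.
#' @param speed optional speed `binned_series`; spikes in invalid speed bins
#'   are dropped.
#' @param band,order passed to [theta_phase()].
#' @return numeric vector of phases in `[0, 2*pi)` with attribute
#'   `n_excluded`, the number of spikes dropped by the epoch/speed filters.
#' @export
spike_theta_phase <- function(lfp, epochs, spike_times, speed = NULL,
                              band = c(5, 11), order = 3) {
  st <- as.numeric(spike_times)
  keep <- rep(TRUE, length(st))
  if (!is.null(epochs)) {
    keep <- in_epochs(st, epochs)
  }
  if (!is.null(speed)) {
    b <- as.integer(floor((st - speed$t0) / speed$dt)) + 1L
    inside <- b >= 1L & b <= length(speed$values)
    keep <- keep & inside
    keep[keep] <- speed$valid[b[keep]]
  }
  ph_un <- theta_phase(lfp, band = band, order = order)
  ts <- (seq_along(ph_un) - 1) / lfp$rate
  ph <- stats::approx(ts, ph_un, xout = st[keep], rule = 2)$y %% (2 * pi)
  attr(ph, "n_excluded") <- sum(!keep)
  ph
}

#' Circular mean direction and resultant length
#'
#' First trigonometric moment of a sample of phases: the preferred phase is
#' the argument and the resultant length R in `[0, 1]` the modulus of the
#' mean unit vector.
#'
#' @param phases numeric vector of angles, radians.
#' @return list with `preferred_phase` (radians in `[0, 2*pi)`), `R`, and
#'   `n`; all `NA` (with `n = 0`) for empty input.
#' @export
circular_stats <- function(phases) {
  phases <- phases[is.finite(phases)]
  n <- length(phases)
  if (n == 0L)
    return(list(preferred_phase = NA_real_, R = NA_real_, n = 0L))
  z <- mean(exp(1i * phases))
  list(preferred_phase = Arg(z) %% (2 * pi), R = Mod(z), n = n)
}

#' Theta index of a spike train
#'
#' From the 5-ms-bin spike autocorrelogram: the mean count in the theta-peak
#' band (100-140 ms) minus the mean count in the trough band (50-70 ms),
#' divided by their sum. Values above `0.2` flag a theta-modulated cell.
#' The counts are raw coincidence counts; the index is scale-free so no
#' rate normalisation is needed.
#'
#' @param spike_times numeric vector, seconds (already restricted to theta
#'   epochs during walking by the caller, e.g. [run_session()]).
#' @param acg_bin autocorrelogram bin, seconds (default 0.005).
#' @param min_spikes minimum spike count below which the index is `NA`
#'   (default 100).
#' @return list with `theta_index` in `[-1, 1]` (or `NA`) and
#'   `theta_modulated` (logical, `NA` when undefined).
#' @export
theta_index <- function(spike_times, acg_bin = 0.005, min_spikes = 100) {
  if (length(spike_times) < min_spikes)
    return(list(theta_index = NA_real_, theta_modulated = NA))
  a <- spike_acg(spike_times, bin = acg_bin, max_lag = 0.15)
  lag_hi <- seq_along(a) * acg_bin           # right edge of each bin
  peak <- mean(a[lag_hi > 0.100 & lag_hi <= 0.140])
  trough <- mean(a[lag_hi > 0.050 & lag_hi <= 0.070])
  idx <- if (peak + trough == 0) 0 else (peak - trough) / (peak + trough)
  list(theta_index = idx, theta_modulated = is_theta_modulated(idx))
}

#' Theta-modulation decision rule
#'
#' A cell is theta-modulated when its theta index exceeds the threshold
#' (0.2), non-modulated otherwise.
#'
#' @param index theta index in `[-1, 1]`.
#' @param threshold decision threshold (default 0.2).
#' @return logical (`NA` for undefined indices).
#' @export
is_theta_modulated <- function(index, threshold = 0.2) {
  ifelse(is.finite(index), index > threshold, NA)
}
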