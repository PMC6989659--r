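#' @name speed_coding
#' @title Speed scores, shuffle nulls, slopes, information and temporal shifts
#'
#' @description
#' The core speed-representation statistics. The speed score of a cell is
#' the Pearson correlation between its smoothed instantaneous firing rate
#' and the animal's smoothed running speed over walking-band bins. Its
#' significance is judged against a pooled null built from circular
#' time-shifts of each spike train (100 per cell, shift uniform between
#' 30 s and session length minus 30 s): scores above the pooled 99th
#' percentile define p-Speed cells, below the 1st percentile n-Speed cells.
#' Speed slope (OLS, Hz per cm/s), normalised slope (rate divided by its
#' mean first), Skaggs-style speed information over a 2-50 cm/s tuning curve
#' with 4-cm/s bins, and the temporal-shift curve (rate correlated against
#' future/past speed, lags -1536..+1536 ms in 25.6-ms steps) complete the
#' per-cell profile.
NULL

#' Instantaneous firing rate on the analysis grid
#'
#' Spike counts per bin divided by the bin width, Gaussian-smoothed with the
#' same kernel policy as the speed series.
#'
#' @param spike_times numeric vector, seconds.
#' @param duration session duration in seconds.
#' @param dt bin width, seconds (default 0.0256).
#' @param sd Gaussian SD, seconds (default 0.512); `0` skips smoothing.
#' @return a `binned_series` of rate in Hz, all bins valid.
#' @export
instantaneous_rate <- function(spike_times, duration, dt = 0.0256, sd = 0.512) {
  n <- as.integer(floor(duration / dt))
  b <- as.integer(floor(spike_times / dt)) + 1L
  b <- b[b >= 1L & b <= n]
  counts <- tabulate(b, n)
  rate <- binned_series(counts / dt, dt = dt)
  if (sd > 0) rate <- gaussian_smooth(rate, sd = sd)
  rate
}

# jointly valid (rate, speed) pairs with speed taken k bins in the future;
# the speed mask is evaluated at the speed timestamp, rate bins shifted off
# the session edge are dropped.
shifted_pairs <- function(rate, speed, k = 0L) {
  check_aligned(rate, speed)
  n <- length(rate$values)
  i <- seq_len(n)
  j <- i + k
  ok <- j >= 1L & j <= n
  i <- i[ok]; j <- j[ok]
  use <- rate$valid[i] & speed$valid[j]
  list(f = rate$values[i[use]], v = speed$values[j[use]])
}

shifted_speed_cor <- function(rate, speed, k = 0L) {
  p <- shifted_pairs(rate, speed, k)
  if (length(p$v) < 2L) return(NA_real_)
  safe_cor(p$f, p$v)
}

#' Speed score of a cell
#'
#' Pearson product-moment correlation between instantaneous firing rate and
#' running speed over walking-band bins, on a scale from -1 to 1. Zero
#' variance in either series yields `NA` (flagged undefined, not 0).
#'
#' @param rate a rate `binned_series` from [instantaneous_rate()].
#' @param speed a speed `binned_series` from [compute_speed()].
#' @param min_bins minimum number of jointly valid bins (default 100).
#' @return the speed score (numeric scalar, possibly `NA`).
#' @export
speed_score <- function(rate, speed, min_bins = 100) {
  check_aligned(rate, speed)
  if (sum(rate$valid & speed$valid) < min_bins)
    return(NA_real_)
  shifted_speed_cor(rate, speed, 0L)
}

#' Circular-shuffle null distribution of speed scores
#'
#' Each surrogate circularly time-shifts the spike train by a random
#' interval drawn uniformly between `margin` and `duration - margin`
#' (wrapping the end of the session to the beginning), then re-runs the full
#' rate pipeline (binning and Gaussian smoothing) and recomputes the speed
#' score. Speed itself is untouched by spike shifts. Spike count is
#' preserved exactly by every surrogate.
#'
#' @inheritParams instantaneous_rate
#' @param speed speed `binned_series`.
#' @param n number of surrogates (default 100).
#' @param margin minimum shift, seconds (default 30).
#' @param seed optional integer seed for reproducible surrogates.
#' @param min_bins passed to [speed_score()].
#' @return numeric vector of `n` shuffled speed scores.
#' @export
shuffle_null <- function(spike_times, speed, duration, n = 100, margin = 30,
                         seed = NULL, dt = 0.0256, sd = 0.512,
                         min_bins = 100) {
  if (duration <= 2 * margin)
    stop("session too short for circular shuffling (need > ", 2 * margin, " s)")
  if (!is.null(seed)) set.seed(seed)
  shifts <- stats::runif(n, margin, duration - margin)
  vapply(shifts, function(s) {
    st <- (spike_times + s) %% duration
    r <- instantaneous_rate(st, duration, dt = dt, sd = sd)
    speed_score(r, speed, min_bins = min_bins)
  }, numeric(1))
}

#' Classify speed cells against a pooled shuffle distribution
#'
#' The null scores of all cells are pooled; cells whose observed score
#' strictly exceeds the pooled 99th percentile are p-Speed, cells strictly
#' below the pooled 1st percentile are n-Speed, the rest non-speed. A
#' per-cell mode uses each cell's own percentiles instead.
#'
#' @param scores numeric vector of observed speed scores, one per cell.
#' @param null_scores list of numeric vectors (one per cell) or a single
#'   pooled numeric vector of shuffled scores.
#' @param probs the two percentile levels (default `c(0.01, 0.99)`).
#' @param pooled pool nulls across cells (default `TRUE`, the population
#'   rule) or threshold each cell against its own null.
#' @return list with `class` (factor `p-Speed`/`n-Speed`/`non-speed`, `NA`
#'   for undefined scores) and `thresholds` (lower, upper; a 2-column matrix
#'   in per-cell mode).
#' @export
classify_speed_cells <- function(scores, null_scores, probs = c(0.01, 0.99),
                                 pooled = TRUE) {
  lv <- c("p-Speed", "n-Speed", "non-speed")
  if (pooled) {
    pool <- unlist(null_scores, use.names = FALSE)
    thr <- stats::quantile(pool, probs, na.rm = TRUE, names = FALSE)
    cls <- ifelse(scores > thr[2], "p-Speed",
                  ifelse(scores < thr[1], "n-Speed", "non-speed"))
    list(class = factor(cls, levels = lv), thresholds = thr)
  } else {
    stopifnot(is.list(null_scores), length(null_scores) == length(scores))
    thr <- t(vapply(null_scores, stats::quantile, numeric(2),
                    probs = probs, na.rm = TRUE, names = FALSE))
    cls <- ifelse(scores > thr[, 2], "p-Speed",
                  ifelse(scores < thr[, 1], "n-Speed", "non-speed"))
    list(class = factor(cls, levels = lv), thresholds = thr)
  }
}

#' Speed slope and normalised speed slope
#'
#' Ordinary least-squares slope of instantaneous firing rate on running
#' speed over walking-band bins, in Hz/(cm/s). The normalised slope divides
#' the rate by its mean over the same bins first (units s/cm).
#'
#' @inheritParams speed_score
#' @param lag optional temporal lag, seconds (rounded to whole bins), at
#'   which the regression is evaluated: rate at `t` against speed at
#'   `t + lag`. The default 0 is the conventional speed slope; passing a
#'   cell's preferred temporal shift gives the lag-aligned slope used for
#'   parameter recovery of lagged speed drives.
#' @return list with `slope`, `norm_slope`, and `mean_rate` (Hz, over the
#'   masked bins); `NA` slopes when speed has zero variance.
#' @export
speed_slope <- function(rate, speed, lag = 0) {
  p <- shifted_pairs(rate, speed, as.integer(round(lag / rate$dt)))
  f <- p$f; v <- p$v
  if (length(v) < 2L || stats::var(v) == 0)
    return(list(slope = NA_real_, norm_slope = NA_real_,
                mean_rate = mean(f)))
  slope <- stats::cov(f, v) / stats::var(v)
  mr <- mean(f)
  list(slope = slope,
       norm_slope = if (mr > 0) slope / mr else NA_real_,
       mean_rate = mr)
}

#' Skaggs information of a tuning curve
#'
#' Information per spike `sum_i p_i (lambda_i/lambda) log2(lambda_i/lambda)`
#' and per second `sum_i p_i lambda_i log2(lambda_i/lambda)`, with
#' `0 * log 0 := 0`. The identity `per_sec = lambda * per_spike` holds
#' exactly. Shared by the speed, spatial and directional variants.
#'
#' @param p occupancy probabilities (summing to 1 over occupied bins).
#' @param lambda per-bin mean firing rates, Hz.
#' @param lambda_bar overall mean firing rate, Hz.
#' @return list with `per_spike` (bits/spike) and `per_sec` (bits/s); both
#'   `NA` when `lambda_bar` is 0.
#' @export
skaggs_information <- function(p, lambda, lambda_bar) {
  stopifnot(length(p) == length(lambda))
  if (!is.finite(lambda_bar) || lambda_bar <= 0)
    return(list(per_spike = NA_real_, per_sec = NA_real_))
  ratio <- lambda / lambda_bar
  term <- ifelse(p > 0 & lambda > 0, p * lambda * log2(ratio), 0)
  per_sec <- sum(term)
  list(per_spike = per_sec / lambda_bar, per_sec = per_sec)
}

#' Speed information of a cell
#'
#' Builds the rate-vs-speed tuning curve (bins of 4 cm/s from 2 to 50 cm/s)
#' from walking-band bins and evaluates the Skaggs information measures on
#' it. Empty speed bins are excluded from the occupancy renormalisation.
#'
#' @inheritParams speed_score
#' @param edges speed-bin edges, cm/s (default `seq(2, 50, by = 4)`).
#' @return list with `per_spike`, `per_sec`, and `tuning` (data frame with
#'   `lo`, `hi`, `p`, `lambda` per occupied bin, plus attribute
#'   `mean_rate`).
#' @export
speed_information <- function(rate, speed, edges = seq(2, 50, by = 4)) {
  check_aligned(rate, speed)
  use <- rate$valid & speed$valid
  f <- rate$values[use]; v <- speed$values[use]
  if (length(v) == 0L)
    return(list(per_spike = NA_real_, per_sec = NA_real_, tuning = NULL))
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  bin[bin < 1L | bin >= length(edges)] <- NA_integer_
  ok <- !is.na(bin)
  cnt <- tabulate(bin[ok], length(edges) - 1L)
  occupied <- which(cnt > 0L)
  p <- cnt[occupied] / sum(cnt)
  lam <- vapply(occupied, function(b) mean(f[ok][bin[ok] == b]), numeric(1))
  lam_bar <- sum(p * lam)
  info <- skaggs_information(p, lam, lam_bar)
  tuning <- data.frame(lo = edges[occupied], hi = edges[occupied + 1L],
                       p = p, lambda = lam)
  attr(tuning, "mean_rate") <- lam_bar
  c(info, list(tuning = tuning))
}

#' Temporal-shift curve and preferred temporal shift
#'
#' Correlates the firing rate at time `t` with the running speed at
#' `t + tau` for lags `tau` from `-max_shift` to `+max_shift` in steps of
#' one bin. Positive preferred shifts mean the rate predicts future speed
#' (prospective coding); negative shifts are retrospective. The zero-lag
#' entry is the speed score bit-for-bit (shared code path). Cells whose
#' argmax lies on either boundary of the lag window are flagged excluded.
#'
#' @inheritParams speed_score
#' @param max_shift half-width of the lag window, seconds (default 1.536).
#' @return list with `tau` (s), `r` (correlation per lag), `preferred_shift`
#'   (s, `NA` when excluded or undefined), `excluded` (logical), and
#'   `normalized` (`r / r(0)`, `NA` when `r(0)` is 0 or undefined).
#' @export
temporal_shift_curve <- function(rate, speed, max_shift = 1.536) {
  check_aligned(rate, speed)
  kmax <- as.integer(round(max_shift / rate$dt))
  ks <- seq(-kmax, kmax)
  r <- vapply(ks, function(k) shifted_speed_cor(rate, speed, k), numeric(1))
  tau <- ks * rate$dt
  if (all(is.na(r)))
    return(list(tau = tau, r = r, preferred_shift = NA_real_,
                excluded = NA, normalized = rep(NA_real_, length(r))))
  imax <- which.max(r)
  excluded <- imax == 1L || imax == length(ks)
  r0 <- r[ks == 0L]
  normalized <- if (is.na(r0) || r0 == 0) rep(NA_real_, length(r)) else r / r0
  list(tau = tau, r = r,
       preferred_shift = if (excluded) NA_real_ else tau[imax],
       excluded = excluded, normalized = normalized)
}

#' Full per-cell speed-representation analysis
#'
#' Runs the whole speed pipeline for one unit: instantaneous rate, speed
#' score, circular-shuffle null, slope and normalised slope, speed
#' information, and the temporal-shift curve. Returns a classed object with
#' `print`, `summary`, `coef` and `plot` methods. Classification into
#' p-/n-Speed is a population decision; see [classify_speed_cells()] or
#' [run_session()].
#'
#' @inheritParams shuffle_null
#' @param n_shuffles surrogates for the per-cell null (default 100).
#' @param max_shift temporal-shift half-window, seconds (default 1.536).
#' @param min_bins minimum jointly valid bins for a defined score.
#' @return an object of class `speed_cell_fit`.
#' @export
speed_cell_analysis <- function(spike_times, speed, duration,
                                dt = 0.0256, sd = 0.512, n_shuffles = 100,
                                margin = 30, max_shift = 1.536,
                                min_bins = 100, seed = NULL) {
  rate <- instantaneous_rate(spike_times, duration, dt = dt, sd = sd)
  score <- speed_score(rate, speed, min_bins = min_bins)
  sl <- speed_slope(rate, speed)
  info <- speed_information(rate, speed)
  shift <- temporal_shift_curve(rate, speed, max_shift = max_shift)
  nulls <- shuffle_null(spike_times, speed, duration, n = n_shuffles,
                        margin = margin, seed = seed, dt = dt, sd = sd,
                        min_bins = min_bins)
  structure(list(
    n_spikes = length(spike_times), duration = duration,
    speed_score = score, slope = sl$slope, norm_slope = sl$norm_slope,
    mean_rate = sl$mean_rate,
    info_per_spike = info$per_spike, info_per_sec = info$per_sec,
    tuning = info$tuning, shift = shift,
    preferred_shift = shift$preferred_shift,
    shift_excluded = shift$excluded,
    null_scores = nulls,
    params = list(dt = dt, sd = sd, n_shuffles = n_shuffles,
                  margin = margin, max_shift = max_shift)),
    class = "speed_cell_fit")
}

#' @export
print.speed_cell_fit <- function(x, ...) {
  cat("Per-cell speed-representation analysis\n")
  cat(sprintf("  spikes: %d over %.1f s (mean rate %.3g Hz on walking bins)\n",
              x$n_spikes, x$duration, x$mean_rate))
  cat(sprintf("  speed score: %.4f   slope: %.4g Hz/(cm/s)   norm. slope: %.4g s/cm\n",
              x$speed_score, x$slope, x$norm_slope))
  cat(sprintf("  speed information: %.4g bits/spike, %.4g bits/s\n",
              x$info_per_spike, x$info_per_sec))
  if (isTRUE(x$shift_excluded)) {
    cat("  preferred temporal shift: at lag-window boundary (excluded)\n")
  } else {
    cat(sprintf("  preferred temporal shift: %+.1f ms (%s)\n",
                1000 * x$preferred_shift,
                if (is.na(x$preferred_shift)) "undefined"
                else if (x$preferred_shift > 0) "prospective"
                else if (x$preferred_shift < 0) "retrospective" else "zero lag"))
  }
  cat(sprintf("  shuffle null: %d scores, cell 1st/99th pct %.4f / %.4f\n",
              length(x$null_scores),
              stats::quantile(x$null_scores, 0.01, na.rm = TRUE),
              stats::quantile(x$null_scores, 0.99, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.speed_cell_fit <- function(object, ...) {
  out <- with(object, data.frame(
    n_spikes = n_spikes, mean_rate = mean_rate, speed_score = speed_score,
    slope = slope, norm_slope = norm_slope,
    info_per_spike = info_per_spike, info_per_sec = info_per_sec,
    preferred_shift = preferred_shift, shift_excluded = shift_excluded))
  class(out) <- c("summary.speed_cell_fit", "data.frame")
  out
}

#' @export
coef.speed_cell_fit <- function(object, ...) {
  c(speed_score = object$speed_score, slope = object$slope,
    norm_slope = object$norm_slope)
}

#' @export
plot.speed_cell_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (!is.null(x$tuning))
    graphics::plot((x$tuning$lo + x$tuning$hi) / 2, x$tuning$lambda,
                   type = "b", xlab = "running speed (cm/s)",
                   ylab = "firing rate (Hz)", main = "speed tuning", ...)
  graphics::plot(1000 * x$shift$tau, x$shift$r, type = "l",
                 xlab = "temporal shift (ms)", ylab = "correlation",
                 main = "temporal-shift curve", ...)
  graphics::abline(v = 0, lty = 3)
  if (!is.na(x$preferred_shift))
    graphics::abline(v = 1000 * x$preferred_shift, col = 2)
  invisible(x)
}
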