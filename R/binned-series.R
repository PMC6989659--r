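#' Uniformly binned time series
#'
#' The shared container for instantaneous firing rate, running speed, position
#' and head direction: a vector of per-bin values on a uniform time grid plus
#' a per-bin validity mask. The default bin width is 25.6 ms, the video-frame
#' subdivision used throughout the analysis.
#'
#' @param values numeric vector of per-bin values.
#' @param dt bin width in seconds (default 0.0256).
#' @param t0 time of the left edge of the first bin, seconds.
#' @param valid logical vector, same length as `values`; bins excluded from
#'   analysis are `FALSE`.
#' @return an object of class `binned_series`.
#' @export
binned_series <- function(values, dt = 0.0256, t0 = 0, valid = NULL) {
  stopifnot(dt > 0)
  values <- as.numeric(values)
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.logical(valid) & !is.na(values)
  if (length(valid) != length(values))
    stop("`valid` must match `values` in length")
  structure(list(values = values, dt = dt, t0 = t0, valid = valid),
            class = "binned_series")
}

#' @export
length.binned_series <- function(x) length(x$values)

#' Bin-centre times of a binned series
#' @param x a `binned_series`.
#' @return numeric vector of bin-centre times in seconds.
#' @export
bin_times <- function(x) {
  stopifnot(inherits(x, "binned_series"))
  x$t0 + (seq_along(x$values) - 0.5) * x$dt
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> %d bins x %.4g ms, %d valid (%.1f%%)\n",
              length(x$values), x$dt * 1000, sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!isTRUE(all.equal(a$dt, b$dt)) || !isTRUE(all.equal(a$t0, b$t0)) ||
      length(a$values) != length(b$values))
    stop("binned series are not aligned (dt/t0/length differ)")
  invisible(TRUE)
}

#' Gaussian smoothing of a binned series
#'
#' Convolution with a Gaussian kernel truncated at +/- 4 SD. Near the series
#' edges and around invalid bins the kernel is renormalised over the
#' available valid bins, so the smoother is unbiased for a constant signal
#' everywhere. Invalid bins stay invalid (their values are the renormalised
#' estimate from valid neighbours, usable for display but masked).
#'
#' @param x a `binned_series`.
#' @param sd kernel standard deviation in seconds (default 0.512).
#' @param truncate kernel support half-width in SDs (default 4).
#' @return a `binned_series` with smoothed values and the original mask.
#' @export
gaussian_smooth <- function(x, sd = 0.512, truncate = 4) {
  stopifnot(inherits(x, "binned_series"), sd >= 0)
  if (sd == 0) return(x)
  sd_bins <- sd / x$dt
  h <- max(1L, as.integer(ceiling(truncate * sd_bins)))
  k <- stats::dnorm(seq(-h, h), sd = sd_bins)
  key <- sprintf("g|%.12g|%d", sd_bins, length(x$values))
  v <- x$values
  ok <- x$valid
  v[!ok] <- 0
  num <- conv_same(v, k, key)
  den <- if (all(ok)) cached_ones_conv(k, length(v), key)
  else conv_same(as.numeric(ok), k, key)
  out <- ifelse(den > 0, num / den, NA_real_)
  binned_series(out, dt = x$dt, t0 = x$t0, valid = ok & !is.na(out))
}

.conv_cache <- new.env(parent = emptyenv())

# centred ("same") linear convolution via FFT; n + length(k) padded to a
# composite-friendly size. The kernel transform (and, for fully valid
# series, the edge-normalisation term) is memoised: the analysis pipeline
# re-applies the same kernel thousands of times per session.
conv_same <- function(v, k, key = NULL) {
  n <- length(v); m <- length(k); h <- (m - 1L) %/% 2L
  nf <- stats::nextn(n + m - 1L, c(2, 3, 5))
  fk <- NULL
  if (!is.null(key)) {
    kk <- paste0(key, "|", nf)
    fk <- .conv_cache[[kk]]
  }
  if (is.null(fk)) {
    fk <- stats::fft(c(k, numeric(nf - m)))
    if (!is.null(key)) .conv_cache[[kk]] <- fk
  }
  fv <- stats::fft(c(v, numeric(nf - n)))
  full <- Re(stats::fft(fv * fk, inverse = TRUE)) / nf
  full[(h + 1L):(h + n)]
}

cached_ones_conv <- function(k, n, key) {
  kk <- paste0("ones|", key)
  d <- .conv_cache[[kk]]
  if (is.null(d) || length(d) != n) {
    d <- conv_same(rep(1, n), k, key)
    .conv_cache[[kk]] <- d
  }
  d
}
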