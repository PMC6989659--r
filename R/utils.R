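# Internal helpers shared across modules.

# Spike-train autocorrelogram: counts of positive spike-time lags per bin.
# Returns counts for bins (0, bin], (bin, 2*bin], ..., up to max_lag.
# Two-pointer sweep via findInterval, fully vectorised.
spike_acg <- function(spike_times, bin = 0.001, max_lag = 0.05) {
  st <- sort(as.numeric(spike_times))
  n <- length(st)
  nbins <- as.integer(round(max_lag / bin))
  if (n < 2L) return(integer(nbins))
  hi <- findInterval(st + max_lag, st)
  cnt <- hi - seq_len(n)
  cnt[cnt < 0L] <- 0L
  if (sum(cnt) == 0L) return(integer(nbins))
  j <- sequence(cnt, from = seq_len(n) + 1L)
  i <- rep.int(seq_len(n), cnt)
  d <- st[j] - st[i]
  d <- d[d > 0]
  tabulate(pmin(nbins, as.integer(ceiling(d / bin))), nbins)
}

# Cross-correlogram of post relative to pre over lags in (-max_lag, max_lag].
# Bin b (1-indexed) covers lag ((b - nbins - 1)*bin, (b - nbins)*bin].
spike_ccg <- function(pre, post, bin = 0.001, max_lag = 0.02) {
  pre <- sort(as.numeric(pre)); post <- sort(as.numeric(post))
  nbins <- as.integer(round(max_lag / bin))
  out <- integer(2L * nbins)
  if (length(pre) == 0L || length(post) == 0L) return(out)
  lo <- findInterval(pre - max_lag, post)
  hi <- findInterval(pre + max_lag, post)
  cnt <- hi - lo
  keep <- cnt > 0L
  if (!any(keep)) return(out)
  j <- sequence(cnt[keep], from = lo[keep] + 1L)
  i <- rep.int(which(keep), cnt[keep])
  d <- post[j] - pre[i]
  b <- as.integer(ceiling(d / bin)) + nbins
  b[d == -max_lag] <- 1L          # closed lower edge of the first bin
  b <- b[b >= 1L & b <= 2L * nbins]
  tabulate(b, 2L * nbins)
}

ccg_lag_centres <- function(bin = 0.001, max_lag = 0.02) {
  nbins <- as.integer(round(max_lag / bin))
  (seq_len(2L * nbins) - nbins - 0.5) * bin
}

# Analytic signal by the standard frequency-domain construction: zero the
# negative frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Deterministic per-unit RNG seed derived from (master seed, unit index),
# Lehmer-style so adding units never perturbs earlier ones. Stays < 2^31.
unit_seed <- function(master, i) {
  m <- 2147483647
  s <- ((as.numeric(master) %% m) * 48271 + as.numeric(i) * 104729) %% m
  as.integer(if (s == 0) 1 else s)
}

# Pearson correlation that refuses to silently return NA: zero variance in
# either input is reported as NA with an attribute, matching the contract
# that degenerate scores are flagged, not coerced to 0.
safe_cor <- function(a, b) {
  if (length(a) < 2L) return(NA_real_)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  stats::cor(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE for times inside any [start, end] interval of a sorted, non-overlapping
# epoch matrix.
in_epochs <- function(times, epochs) {
  if (is.null(epochs) || nrow(epochs) == 0) return(rep(FALSE, length(times)))
  edges <- as.vector(t(epochs))            # start1 end1 start2 end2 ...
  idx <- findInterval(times, edges, rightmost.closed = TRUE)
  idx %% 2L == 1L | times %in% epochs[, 2]
}
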