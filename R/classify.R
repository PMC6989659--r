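#' @name cell_classification
#' @title Physiological cell typing
#'
#' @description
#' Excitatory/inhibitory identification by the jitter-based monosynaptic
#' cross-correlogram test and, population-wide, by a linear discriminant on
#' waveform features (trough-to-peak latency and asymmetry index); putative
#' PV- vs SOM-expressing hippocampal interneurons from autocorrelogram
#' burst index and refractory period; putative EC2 stellate vs pyramidal
#' cells from theta-locking decision regions supplied as configuration.
NULL

#' Jitter-based monosynaptic connection test
#'
#' The observed cross-correlogram (1-ms bins over -20..+20 ms) is compared
#' with global 99% acceptance bands built from surrogate data sets in which
#' every spike of both trains is independently jittered on a uniform
#' `[-jitter, +jitter]` interval. The upper band is the 99th percentile of
#' each surrogate's maximum count over the whole lag window (lower band:
#' 1st percentile of the minima). The verdict is `excitatory` when the
#' observed count exceeds the upper band at any 1-ms bin at latency 1-5 ms,
#' `inhibitory` when at least one such bin falls below the lower band, else
#' `none`. For same-electrode pairs the 0-1 ms bin is ignored (superimposed
#' spikes cannot be resolved).
#'
#' @param pre,post spike-time vectors, seconds.
#' @param n_surr number of jitter surrogates (default 1000).
#' @param jitter half-width of the jitter interval, seconds (default
#'   0.005).
#' @param seed optional integer seed.
#' @param same_electrode ignore the 0-1 ms bin (default `FALSE`).
#' @param min_spikes verdict is `none` (insufficient data) below this
#'   count in either train (default 50).
#' @return list of class `ccg_test` with `verdict`, `ccg` (counts), `lags`
#'   (bin centres, s), `upper`, `lower` (global band levels), and
#'   `insufficient` flag.
#' @export
jitter_ccg_test <- function(pre, post, n_surr = 1000, jitter = 0.005,
                            seed = NULL, same_electrode = FALSE,
                            min_spikes = 50) {
  bin <- 0.001; max_lag <- 0.02
  lags <- ccg_lag_centres(bin, max_lag)
  if (length(pre) < min_spikes || length(post) < min_spikes) {
    return(structure(list(verdict = "none", ccg = NULL, lags = lags,
                          upper = NA_real_, lower = NA_real_,
                          insufficient = TRUE), class = "ccg_test"))
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- spike_ccg(pre, post, bin, max_lag)
  nb <- length(lags)
  consider <- rep(TRUE, nb)
  if (same_electrode) consider[lags > 0 & lags < bin] <- FALSE
  # every (pre, post) pair that any surrogate could place inside the lag
  # window lies within max_lag + 2*jitter of the original trains; jittering
  # then only moves each precomputed pair difference by (dq - dp)
  pre <- sort(as.numeric(pre)); post <- sort(as.numeric(post))
  reach <- max_lag + 2 * jitter
  lo <- findInterval(pre - reach, post)
  hi <- findInterval(pre + reach, post)
  cnt <- pmax(0L, hi - lo)
  maxs <- integer(n_surr); mins <- integer(n_surr)
  if (sum(cnt) > 0L) {
    jidx <- sequence(cnt[cnt > 0L], from = lo[cnt > 0L] + 1L)
    iidx <- rep.int(which(cnt > 0L), cnt[cnt > 0L])
    d0 <- post[jidx] - pre[iidx]
    npair <- length(d0)
    # chunk surrogates to bound memory
    chunk <- max(1L, as.integer(2e6 %/% max(1L, npair)))
    done <- 0L
    while (done < n_surr) {
      k <- min(chunk, n_surr - done)
      dp <- matrix(stats::runif(k * length(pre), -jitter, jitter), k)
      dq <- matrix(stats::runif(k * length(post), -jitter, jitter), k)
      d <- rep(d0, each = k) + dq[, jidx] - dp[, iidx]    # k x npair
      b <- as.integer(ceiling(d / bin)) + nb %/% 2L
      ok <- b >= 1L & b <= nb & d != -max_lag
      srow <- rep.int(seq_len(k), npair)
      code <- (srow[ok] - 1L) * nb + b[ok]
      counts <- matrix(tabulate(code, k * nb), nrow = nb)
      counts <- counts[consider, , drop = FALSE]
      maxs[done + seq_len(k)] <- apply(counts, 2, max)
      mins[done + seq_len(k)] <- apply(counts, 2, min)
      done <- done + k
    }
  }
  upper <- stats::quantile(maxs, 0.99, names = FALSE)
  lower <- stats::quantile(mins, 0.01, names = FALSE)
  window <- lags > 0.001 & lags <= 0.005       # latency 1-5 ms, pre -> post
  verdict <- if (any(obs[window] > upper)) "excitatory"
  else if (any(obs[window] < lower)) "inhibitory"
  else "none"
  structure(list(verdict = verdict, ccg = obs, lags = lags, upper = upper,
                 lower = lower, insufficient = FALSE), class = "ccg_test")
}

#' Autocorrelogram burst index and refractory period
#'
#' From the 1-ms spike autocorrelogram: the burst amplitude is the peak
#' count in 0-10 ms minus the baseline (mean count in 40-50 ms); the burst
#' index divides the amplitude by the larger of peak and baseline, so it
#' ranges over `[-1, 1]`. The refractory period is the first bin at which
#' the instantaneous ACG derivative (first differences from 0 ms up to the
#' global ACG peak) exceeds one SD of those derivative values.
#'
#' @param spike_times numeric vector, seconds.
#' @param bin autocorrelogram bin, seconds (default 0.001).
#' @param min_spikes minimum spike count (default 200); otherwise both
#'   features are `NA`.
#' @param peak_search_ms window, ms, in which the global ACG peak for the
#'   derivative is sought (default 50).
#' @return list with `burst_index` and `refractory_ms`.
#' @export
acg_features <- function(spike_times, bin = 0.001, min_spikes = 200,
                         peak_search_ms = 50) {
  if (length(spike_times) < min_spikes)
    return(list(burst_index = NA_real_, refractory_ms = NA_real_))
  a <- spike_acg(spike_times, bin = bin, max_lag = peak_search_ms / 1000)
  lag_ms <- seq_along(a) * bin * 1000          # right edge, ms
  peak <- max(a[lag_ms <= 10])
  baseline <- mean(a[lag_ms > 40 & lag_ms <= 50])
  denom <- max(peak, baseline)
  bi <- if (denom == 0) 0 else (peak - baseline) / denom
  # refractory: derivative from 0 to the global ACG peak
  ipk <- which.max(a)
  refr <- NA_real_
  if (ipk >= 2L) {
    der <- diff(c(0, a[seq_len(ipk)]))         # instantaneous derivative
    s <- stats::sd(der)
    hit <- which(der > s)
    if (length(hit)) refr <- hit[1L] * bin * 1000
  }
  list(burst_index = bi, refractory_ms = refr)
}

#' Classify a hippocampal interneuron as putative PV or SOM
#'
#' PV: positive burst index and refractory period shorter than 7 ms.
#' SOM: negative burst index and refractory period longer than 4 ms.
#' Anything else (including undefined features) is unclassified. A pure
#' function of the two features.
#'
#' @param burst_index numeric in `[-1, 1]`.
#' @param refractory_ms refractory period, ms.
#' @return `"PV"`, `"SOM"` or `"unclassified"`.
#' @export
classify_pv_som <- function(burst_index, refractory_ms) {
  if (!is.finite(burst_index) || !is.finite(refractory_ms))
    return("unclassified")
  if (burst_index > 0 && refractory_ms < 7) return("PV")
  if (burst_index < 0 && refractory_ms > 4) return("SOM")
  "unclassified"
}

#' Waveform-based excitatory/inhibitory separation
#'
#' Units physiologically identified by the jitter test seed a linear
#' discriminant in the (trough-to-peak latency, asymmetry index) plane;
#' every unit is then labelled by its side of the fitted hyperplane. When
#' fewer than `min_labelled` units per class are available the configured
#' fixed boundary is used instead. Units within `margin` of the boundary
#' (in discriminant units) are flagged low-confidence.
#'
#' @param features data frame with columns `trough_to_peak` (ms) and
#'   `asymmetry`.
#' @param labels character vector aligned with `features`: `"excitatory"`,
#'   `"inhibitory"`, or `NA` for unlabelled units.
#' @param min_labelled minimum labelled units per class to fit (default 5).
#' @param fixed_boundary fallback boundary `c(intercept, coef_ttp,
#'   coef_asym)`: units with `intercept + coef_ttp*ttp + coef_asym*asym > 0`
#'   are principal. Default separates at 0.425 ms trough-to-peak.
#' @param margin low-confidence half-width on the discriminant axis
#'   (default 0.1).
#' @return list with `ei` (factor `principal`/`interneuron`/`unclassified`),
#'   `score` (signed distance, positive = principal), `low_confidence`
#'   (logical), and `method` (`"lda"` or `"fixed"`).
#' @export
waveform_ei_separation <- function(features, labels, min_labelled = 5,
                                   fixed_boundary = c(-0.425, 1, 0),
                                   margin = 0.1) {
  stopifnot(all(c("trough_to_peak", "asymmetry") %in% names(features)))
  X <- as.matrix(features[, c("trough_to_peak", "asymmetry")])
  lab <- factor(labels, levels = c("excitatory", "inhibitory"))
  n_e <- sum(lab == "excitatory", na.rm = TRUE)
  n_i <- sum(lab == "inhibitory", na.rm = TRUE)
  if (n_e >= min_labelled && n_i >= min_labelled) {
    fit <- MASS::lda(X[!is.na(lab), , drop = FALSE], grouping = droplevels(lab[!is.na(lab)]))
    proj <- scale(X, center = colMeans(fit$means), scale = FALSE) %*% fit$scaling[, 1]
    # orient so excitatory (principal) side is positive
    me <- mean(proj[which(lab == "excitatory")])
    if (is.finite(me) && me < 0) proj <- -proj
    score <- as.numeric(proj)
    method <- "lda"
  } else {
    score <- fixed_boundary[1] + X %*% fixed_boundary[2:3]
    score <- as.numeric(score)
    method <- "fixed"
  }
  ei <- ifelse(score > 0, "principal", ifelse(score < 0, "interneuron",
                                              "unclassified"))
  lowc <- abs(score) < margin
  list(ei = factor(ei, levels = c("principal", "interneuron", "unclassified")),
       score = score, low_confidence = lowc, method = method)
}

#' Default EC2 stellate/pyramidal decision regions
#'
#' A synthetic placeholder boundary in (preferred theta phase, resultant
#' length) polar space, NOT the published calbindin-calibrated regions
#' (those parameters live in external code unavailable here): pyramidal
#' cells are taken as strongly locked near the theta trough, stellate cells
#' as weakly locked or locked away from the trough. Replace with
#' authoritative regions via the `regions` argument of
#' [classify_ec2_stellate_pyramidal()] for any real inference.
#'
#' @return list of named regions, each `list(phase_lo, phase_hi, r_lo,
#'   r_hi)` with phases in radians (intervals may wrap through 0).
#' @export
ec2_default_regions <- function() {
  list(pyramidal = list(phase_lo = pi / 2, phase_hi = 3 * pi / 2,
                        r_lo = 0.15, r_hi = 1),
       stellate = list(phase_lo = 3 * pi / 2, phase_hi = pi / 2,
                       r_lo = 0.05, r_hi = 1))
}

phase_in <- function(phase, lo, hi) {
  phase <- phase %% (2 * pi)
  if (lo <= hi) phase > lo & phase < hi else phase > lo | phase < hi
}

#' Classify an EC2 principal cell as putative stellate or pyramidal
#'
#' Membership of the (preferred phase, resultant length) point in the
#' configured polar decision regions, evaluated against local EC2 theta.
#' Units outside all regions, or on a region boundary, are unclassified.
#'
#' @param preferred_phase radians, relative to local EC2 theta.
#' @param R resultant length in `[0, 1]`.
#' @param regions region list as from [ec2_default_regions()] (the shipped
#'   default is a documented placeholder, not the published boundary).
#' @return region name or `"unclassified"`.
#' @export
classify_ec2_stellate_pyramidal <- function(preferred_phase, R,
                                            regions = ec2_default_regions()) {
  if (!is.finite(preferred_phase) || !is.finite(R)) return("unclassified")
  for (nm in names(regions)) {
    rg <- regions[[nm]]
    if (phase_in(preferred_phase, rg$phase_lo, rg$phase_hi) &&
        R > rg$r_lo && R < rg$r_hi)
      return(nm)
  }
  "unclassified"
}
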