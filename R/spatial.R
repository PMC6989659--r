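#' @name spatial_coding
#' @title Rate maps, spatial/directional information, gridness
#'
#' @description
#' Two-dimensional firing-rate maps (3-cm bins, occupancy and spike-count
#' maps Gaussian-smoothed separately with SD 3 cm), Skaggs information for
#' the spatial and head-directional variants, the edge-corrected spatial
#' autocorrelogram, and the gridness score contrasting 60/120-degree with
#' 30/90/150-degree rotational correlations of expanding annuli.
NULL

gauss_kernel_1d <- function(sd_bins, truncate = 4) {
  h <- max(1L, as.integer(ceiling(truncate * sd_bins)))
  k <- stats::dnorm(seq(-h, h), sd = sd_bins)
  k / sum(k)
}

# separable 2-D Gaussian smoothing with edge renormalisation
smooth_map <- function(m, sd_bins) {
  k <- gauss_kernel_1d(sd_bins)
  ones <- matrix(1, nrow(m), ncol(m))
  num <- apply(m, 2, conv_same, k = k)
  num <- t(apply(num, 1, conv_same, k = k))
  den <- apply(ones, 2, conv_same, k = k)
  den <- t(apply(den, 1, conv_same, k = k))
  num / den
}

#' Two-dimensional firing-rate map
#'
#' Position and spiking are restricted to running periods (speed above
#' `vmin`), sorted into square bins, and the occupancy (seconds) and
#' spike-count maps are each smoothed with a Gaussian kernel before the
#' rate map is formed as their ratio. Rate is defined only where smoothed
#' occupancy is positive and the bin was visited.
#'
#' @param spike_times numeric vector, seconds.
#' @param x,y smoothed position `binned_series` (cm).
#' @param speed speed `binned_series`; bins with `values > vmin` and valid
#'   tracking are used (`vmin = 2` by default, no upper bound here).
#' @param arena_side cm.
#' @param bin spatial bin size, cm (default 3).
#' @param sd smoothing SD, cm (default 3).
#' @param vmin running-speed floor, cm/s (default 2).
#' @return list of class `rate_map` with matrices `rate`, `occupancy_s`,
#'   `spike_count` (unsmoothed), `visited`, and fields `bin`, `edges`.
#' @export
rate_map <- function(spike_times, x, y, speed, arena_side, bin = 3, sd = 3,
                     vmin = 2) {
  check_aligned(x, y); check_aligned(x, speed)
  # running filter: tracking valid and speed > vmin (mask stored in speed
  # already excludes invalid tracking; re-apply the floor only)
  run <- x$valid & y$valid & is.finite(speed$values) & speed$values > vmin
  if (!any(run)) stop("empty occupancy: no running periods")
  edges <- seq(0, arena_side, by = bin)
  nb <- length(edges) - 1L
  bx <- pmin(nb, pmax(1L, findInterval(x$values, edges, rightmost.closed = TRUE)))
  by <- pmin(nb, pmax(1L, findInterval(y$values, edges, rightmost.closed = TRUE)))
  idx <- (by - 1L) * nb + bx
  occ <- matrix(tabulate(idx[run], nb * nb) * x$dt, nb, nb)
  # spikes mapped to their time bin, kept when that bin passes the filter
  sb <- as.integer(floor(spike_times / x$dt)) + 1L
  sb <- sb[sb >= 1L & sb <= length(run)]
  sb <- sb[run[sb]]
  sc <- matrix(tabulate(idx[sb], nb * nb), nb, nb)
  occ_s <- smooth_map(occ, sd / bin)
  sc_s <- smooth_map(sc, sd / bin)
  visited <- occ > 0
  rate <- ifelse(occ_s > 0 & visited, sc_s / occ_s, NA_real_)
  structure(list(rate = rate, occupancy_s = occ, spike_count = sc,
                 visited = visited, bin = bin, edges = edges),
            class = "rate_map")
}

#' Spatial information of a rate map
#'
#' Occupancy probabilities and per-bin rates from a [rate_map()], fed to
#' [skaggs_information()].
#'
#' @param map a `rate_map`.
#' @return list with `per_spike` (bits/spike) and `per_sec` (bits/s).
#' @export
spatial_information <- function(map) {
  use <- map$visited & is.finite(map$rate)
  p <- map$occupancy_s[use] / sum(map$occupancy_s[use])
  lam <- map$rate[use]
  skaggs_information(p, lam, sum(p * lam))
}

#' Head-directional tuning curve and information
#'
#' Head direction and spiking sorted into 6-degree bins; the directional
#' rate is spike count over dwell time per bin (no smoothing), and the
#' information measures use the shared Skaggs formulas. Unvisited direction
#' bins are excluded.
#'
#' @param spike_times numeric vector, seconds.
#' @param hd head-direction `binned_series` (radians).
#' @param speed optional speed series for the running filter (> `vmin`).
#' @param bin_deg directional bin size, degrees (default 6).
#' @param vmin running-speed floor, cm/s (default 2).
#' @return list with `tuning` (data frame `dir_lo`, `dir_hi` in degrees,
#'   `p`, `lambda`), `per_spike`, `per_sec`, and `preferred_direction`
#'   (degrees, circular mean weighted by rate).
#' @export
directional_rate_map <- function(spike_times, hd, speed = NULL, bin_deg = 6,
                                 vmin = 2) {
  run <- hd$valid
  if (!is.null(speed)) {
    check_aligned(hd, speed)
    run <- run & is.finite(speed$values) & speed$values > vmin
  }
  nb <- as.integer(round(360 / bin_deg))
  ang <- hd$values %% (2 * pi)
  b <- pmin(nb, as.integer(floor(ang / (2 * pi) * nb)) + 1L)
  occ <- tabulate(b[run], nb) * hd$dt
  sb <- as.integer(floor(spike_times / hd$dt)) + 1L
  sb <- sb[sb >= 1L & sb <= length(run)]
  sb <- sb[run[sb]]
  sc <- tabulate(b[sb], nb)
  vis <- occ > 0
  p <- occ[vis] / sum(occ[vis])
  lam <- sc[vis] / occ[vis]
  info <- skaggs_information(p, lam, sum(p * lam))
  centre <- (which(vis) - 0.5) * bin_deg
  z <- sum(lam * exp(1i * centre / 180 * pi))
  tuning <- data.frame(dir_lo = (which(vis) - 1) * bin_deg,
                       dir_hi = which(vis) * bin_deg, p = p, lambda = lam)
  c(info, list(tuning = tuning,
               preferred_direction = (Arg(z) * 180 / pi) %% 360))
}

#' Spatial autocorrelogram of a rate map
#'
#' For each spatial lag the Pearson correlation (with the standard
#' edge-effect correction) over the bins where the rate is defined in both
#' the original and the shifted copy; lags with fewer than `min_overlap`
#' such bins are undefined.
#'
#' @param map a `rate_map`, or a plain numeric matrix of rates (`NA` for
#'   undefined bins).
#' @param min_overlap minimum overlap count `n` per lag (default 20).
#' @return list of class `autocorr_map` with `r` (matrix over lags), `n`
#'   (overlap counts), and `bin` (cm, when known).
#' @export
autocorrelogram_2d <- function(map, min_overlap = 20) {
  m <- if (inherits(map, "rate_map")) map$rate else map
  bin <- if (inherits(map, "rate_map")) map$bin else attr(map, "bin") %||% 1
  nr <- nrow(m); nc <- ncol(m)
  lags_x <- -(nr - 1L):(nr - 1L)
  lags_y <- -(nc - 1L):(nc - 1L)
  r <- matrix(NA_real_, length(lags_x), length(lags_y))
  nmat <- matrix(0L, length(lags_x), length(lags_y))
  def <- is.finite(m)
  for (a in seq_along(lags_x)) {
    tx <- lags_x[a]
    i1 <- max(1L, 1L + tx):min(nr, nr + tx)   # rows of m overlapping m shifted by tx
    i2 <- i1 - tx
    if (length(i1) == 0L) next
    for (b in seq_along(lags_y)) {
      ty <- lags_y[b]
      j1 <- max(1L, 1L + ty):min(nc, nc + ty)
      if (length(j1) == 0L) next
      j2 <- j1 - ty
      u <- m[i1, j1, drop = FALSE]; w <- m[i2, j2, drop = FALSE]
      ok <- def[i1, j1, drop = FALSE] & def[i2, j2, drop = FALSE]
      n <- sum(ok)
      nmat[a, b] <- n
      if (n < min_overlap) next
      uu <- u[ok]; ww <- w[ok]
      su <- sum(uu); sw <- sum(ww)
      num <- n * sum(uu * ww) - su * sw
      den <- sqrt(n * sum(uu^2) - su^2) * sqrt(n * sum(ww^2) - sw^2)
      if (den > 0) r[a, b] <- num / den
    }
  }
  structure(list(r = r, n = nmat, bin = bin,
                 centre = c(nr, nc)),        # index of zero lag
            class = "autocorr_map")
}

# bilinear interpolation of matrix m at fractional (row, col) coordinates
bilinear <- function(m, ri, ci) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  out <- rep(NA_real_, length(ri))
  ok <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
  if (!any(ok)) return(out)
  i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
  i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
  v <- (1 - fr[ok]) * (1 - fc[ok]) * m[i00] +
    fr[ok] * (1 - fc[ok]) * m[i10] +
    (1 - fr[ok]) * fc[ok] * m[i01] +
    fr[ok] * fc[ok] * m[i11]
  out[ok] <- v
  out
}

#' Gridness score of a spatial autocorrelogram
#'
#' The radius of the central peak is the first local minimum of the
#' correlation-vs-distance curve or the first crossing below 0.2, whichever
#' comes first. Expanding annuli (inner radius the central-peak radius,
#' outer radius growing by one map bin from `central + annulus_min` to the
#' arena width minus `annulus_cap`) are each correlated with their own
#' rotations at 30, 60, 90, 120 and 150 degrees (bilinear interpolation
#' about the centre, undefined bins excluded pairwise). Each annulus scores
#' `min(r60, r120) - max(r30, r90, r150)`; the gridness score is the
#' maximum over annuli.
#'
#' @param acmap an `autocorr_map` from [autocorrelogram_2d()].
#' @param arena_side arena width, cm, capping the outer annulus radius.
#' @param annulus_min,annulus_cap margins added to the central radius and
#'   subtracted from the arena width, cm (default 10 each).
#' @return list of class `gridness_result` with `gridness`,
#'   `central_radius` (cm), and `annuli` (data frame of outer radius and
#'   score); `gridness` is `NA` when no valid annulus exists.
#' @export
gridness <- function(acmap, arena_side, annulus_min = 10, annulus_cap = 10) {
  r <- acmap$r
  bin <- acmap$bin
  ctr <- acmap$centre
  nr <- nrow(r); nc <- ncol(r)
  ri <- row(r) - ctr[1]; ci <- col(r) - ctr[2]
  dist <- sqrt(ri^2 + ci^2) * bin
  # correlation vs distance (rings one bin wide)
  dmax <- max(dist)
  dgrid <- seq(bin, dmax, by = bin)
  prof <- vapply(dgrid, function(d)
    mean(r[dist > d - bin & dist <= d], na.rm = TRUE), numeric(1))
  central <- NA_real_
  for (k in seq_along(prof)) {
    if (!is.finite(prof[k])) next
    if (prof[k] < 0.2) { central <- dgrid[k]; break }
    if (k > 1 && k < length(prof) &&
        is.finite(prof[k - 1]) && is.finite(prof[k + 1]) &&
        prof[k] < prof[k - 1] && prof[k] < prof[k + 1]) {
      central <- dgrid[k]; break
    }
  }
  if (!is.finite(central))
    return(structure(list(gridness = NA_real_, central_radius = NA_real_,
                          annuli = NULL), class = "gridness_result"))
  outer_radii <- seq(central + annulus_min, arena_side - annulus_cap,
                     by = bin)
  outer_radii <- outer_radii[outer_radii > central]
  angles <- c(30, 60, 90, 120, 150) * pi / 180
  scores <- rep(NA_real_, length(outer_radii))
  for (k in seq_along(outer_radii)) {
    sel <- which(dist > central & dist <= outer_radii[k] & is.finite(r))
    if (length(sel) < 20L) next
    rr <- row(r)[sel]; cc <- col(r)[sel]
    base_v <- r[sel]
    cors <- vapply(angles, function(a) {
      dr <- rr - ctr[1]; dc <- cc - ctr[2]
      rrot <- ctr[1] + dr * cos(a) - dc * sin(a)
      crot <- ctr[2] + dr * sin(a) + dc * cos(a)
      rv <- bilinear(r, rrot, crot)
      ok <- is.finite(rv) & is.finite(base_v)
      if (sum(ok) < 20L) return(NA_real_)
      safe_cor(base_v[ok], rv[ok])
    }, numeric(1))
    if (any(!is.finite(cors))) next
    scores[k] <- min(cors[c(2, 4)]) - max(cors[c(1, 3, 5)])
  }
  g <- if (all(!is.finite(scores))) NA_real_ else max(scores, na.rm = TRUE)
  structure(list(gridness = g, central_radius = central,
                 annuli = data.frame(outer = outer_radii, score = scores)),
            class = "gridness_result")
}

#' @export
print.gridness_result <- function(x, ...) {
  cat(sprintf("<gridness> score %.3f (central peak radius %.1f cm, %d annuli)\n",
              x$gridness, x$central_radius,
              if (is.null(x$annuli)) 0L else nrow(x$annuli)))
  invisible(x)
}
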