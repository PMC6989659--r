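#' @name session_io
#' @title Neuroscope-style session files and tabular outputs
#'
#' @description
#' A session directory in the classic Neuroscope layout holds, per shank, a
#' spike-sample file (`<base>.res.N`, one acquisition-clock integer per
#' line) and a cluster file (`<base>.clu.N`, first line the number of
#' clusters, then one cluster id per spike; ids 0 and 1 are reserved for
#' artifact and noise and are dropped), a position file (`<base>.whl`,
#' whitespace-separated `fx fy rx ry` per video frame, -1 marking missing
#' samples) and a flat-binary 16-bit little-endian interleaved LFP file
#' (`<base>.eeg`). A session-layout config declares the sampling rates,
#' channel-to-layer map, pixel scale and arena geometry.
NULL

#' Session-layout configuration
#'
#' @param sample_rate acquisition clock, Hz (default 20000).
#' @param lfp_rate LFP sampling rate, Hz (default 1250).
#' @param video_rate tracking frame rate, Hz (default 30).
#' @param px_to_cm pixel-to-cm scale applied to position files (default 1;
#'   the emulated rigs use ~0.4 cm/pixel).
#' @param arena_side arena side length, cm.
#' @param channels character vector of region/layer labels, one per LFP
#'   channel, in file order.
#' @param shank_regions character vector mapping shank number to
#'   region/layer (recycled).
#' @return a list of class `session_layout`.
#' @export
session_layout <- function(sample_rate = 20000, lfp_rate = 1250,
                           video_rate = 30, px_to_cm = 1, arena_side = 120,
                           channels = "EC3", shank_regions = "CA1") {
  structure(list(sample_rate = sample_rate, lfp_rate = lfp_rate,
                 video_rate = video_rate, px_to_cm = px_to_cm,
                 arena_side = arena_side, channels = channels,
                 shank_regions = shank_regions),
            class = "session_layout")
}

#' In-memory session bundle
#'
#' The uniform container all analyses consume: trajectory, LFP channels,
#' spike trains, arena geometry and duration. Validates that spike times lie
#' in `[0, duration]` and trajectory timestamps strictly increase.
#'
#' @param session_id character label.
#' @param arena_side cm.
#' @param trajectory data frame `t, fx, fy, rx, ry` (cm, `NA` missing).
#' @param lfp named list of LFP channels (`samples`, `rate`,
#'   `region_layer`).
#' @param units list of spike trains (`unit_id`, `spike_times`,
#'   `region_layer`, `shank`, optional `waveform`).
#' @param duration seconds (> 0).
#' @return a list of class `session_bundle`.
#' @export
session_bundle <- function(session_id, arena_side, trajectory, lfp, units,
                           duration) {
  stopifnot(duration > 0)
  if (any(diff(trajectory$t) <= 0))
    stop("trajectory timestamps must be strictly increasing")
  for (u in units) {
    if (length(u$spike_times) &&
        (min(u$spike_times) < 0 || max(u$spike_times) > duration))
      stop("spike times outside [0, duration] for unit ", u$unit_id)
    if (is.unsorted(u$spike_times))
      stop("spike times not sorted for unit ", u$unit_id)
  }
  structure(list(session_id = session_id, arena_side = arena_side,
                 trajectory = trajectory, lfp = lfp, units = units,
                 duration = duration),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %s: %.1f s, %d units, %d LFP channel(s), arena %g cm\n",
              x$session_id, x$duration, length(x$units), length(x$lfp),
              x$arena_side))
  invisible(x)
}

session_base <- function(path) {
  whl <- list.files(path, pattern = "\\.whl$", full.names = TRUE)
  if (length(whl) != 1L)
    stop("expected exactly one .whl position file in ", path)
  sub("\\.whl$", "", whl)
}

#' Read a Neuroscope-style session directory
#'
#' @param path session directory.
#' @param config a [session_layout()].
#' @return a validated [session_bundle()]. Spike samples are converted from
#'   the acquisition clock to seconds; cluster ids 0 and 1 (artifact/noise)
#'   are dropped; spike samples beyond the LFP duration raise a warning and
#'   are clamped.
#' @export
read_session <- function(path, config = session_layout()) {
  base <- session_base(path)
  sid <- basename(base)
  # position
  pos <- utils::read.table(paste0(base, ".whl"))
  if (ncol(pos) < 4L) stop("malformed position file: need 4 columns")
  pos[pos == -1] <- NA                     # the -1 sentinel flags missing samples
  traj <- data.frame(t = (seq_len(nrow(pos)) - 1) / config$video_rate,
                     fx = pos[[1]] * config$px_to_cm,
                     fy = pos[[2]] * config$px_to_cm,
                     rx = pos[[3]] * config$px_to_cm,
                     ry = pos[[4]] * config$px_to_cm)
  class(traj) <- c("trajectory", "data.frame")
  # LFP
  lfp <- list()
  eeg_file <- paste0(base, ".eeg")
  lfp_dur <- NA_real_
  if (file.exists(eeg_file)) {
    nch <- length(config$channels)
    raw <- readBin(eeg_file, "integer", n = file.size(eeg_file) / 2L,
                   size = 2L, signed = TRUE, endian = "little")
    nsamp <- length(raw) %/% nch
    m <- matrix(raw[seq_len(nsamp * nch)], nrow = nch)
    lfp <- lapply(seq_len(nch), function(ch)
      list(samples = as.numeric(m[ch, ]), rate = config$lfp_rate,
           region_layer = config$channels[ch]))
    names(lfp) <- make.unique(config$channels)
    lfp_dur <- nsamp / config$lfp_rate
  }
  duration <- max(max(traj$t), lfp_dur, na.rm = TRUE)
  # spikes, per shank
  res_files <- sort(list.files(path, pattern = "\\.res\\.[0-9]+$",
                               full.names = TRUE))
  units <- list()
  for (rf in res_files) {
    shank <- as.integer(sub(".*\\.res\\.", "", rf))
    cf <- sub("\\.res\\.", ".clu.", rf)
    if (!file.exists(cf)) stop("missing cluster file: ", cf)
    samples <- scan(rf, what = numeric(), quiet = TRUE)
    clu_raw <- scan(cf, what = integer(), quiet = TRUE)
    if (length(clu_raw) != length(samples) + 1L)
      stop("malformed cluster file (count line mismatch): ", cf)
    clu <- clu_raw[-1L]
    st_all <- samples / config$sample_rate
    if (any(st_all > duration + 1e-9)) {
      warning("spike sample(s) beyond session duration in shank ", shank,
              "; clamped")
      st_all <- pmin(st_all, duration)
    }
    region <- rep_len(config$shank_regions, shank)[shank]
    for (cid in sort(unique(clu[clu >= 2L]))) {
      st <- sort(st_all[clu == cid])
      units[[length(units) + 1L]] <-
        list(unit_id = sprintf("sh%d_c%d", shank, cid),
             spike_times = st, region_layer = region, shank = shank)
    }
  }
  session_bundle(session_id = sid, arena_side = config$arena_side,
                 trajectory = traj, lfp = lfp, units = units,
                 duration = duration)
}

#' Write a session bundle as a Neuroscope-style directory
#'
#' The inverse of [read_session()]: positions to `.whl` (missing samples as
#' -1), spikes to per-shank `.res.N`/`.clu.N` (all units written as cluster
#' ids >= 2), LFP to a flat int16 `.eeg`. LFP samples are scaled to use the
#' int16 range.
#'
#' @param session a [session_bundle()].
#' @param path output directory (created if needed).
#' @param config a [session_layout()]; pixel scale and rates are taken from
#'   it.
#' @return the path, invisibly.
#' @export
write_session <- function(session, path, config = session_layout()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(path, session$session_id)
  tr <- session$trajectory
  pos <- cbind(tr$fx, tr$fy, tr$rx, tr$ry) / config$px_to_cm
  pos[!is.finite(pos)] <- -1
  utils::write.table(format(pos, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     paste0(base, ".whl"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (length(session$lfp)) {
    mats <- lapply(session$lfp, function(ch) ch$samples)
    m <- do.call(rbind, mats)
    scale <- max(abs(m), 1e-12)
    ints <- as.integer(round(m / scale * 30000))
    writeBin(as.vector(ints), paste0(base, ".eeg"), size = 2L,
             endian = "little")
  }
  shanks <- unique(vapply(session$units, `[[`, numeric(1), "shank"))
  for (sh in shanks) {
    us <- Filter(function(u) u$shank == sh, session$units)
    samp <- integer(0); clu <- integer(0)
    for (k in seq_along(us)) {
      s <- as.integer(round(us[[k]]$spike_times * config$sample_rate))
      samp <- c(samp, s)
      clu <- c(clu, rep(k + 1L, length(s)))     # ids >= 2 are real units
    }
    o <- order(samp)
    writeLines(as.character(samp[o]), sprintf("%s.res.%d", base, sh))
    writeLines(as.character(c(length(unique(clu)) + 2L, clu[o])),
               sprintf("%s.clu.%d", base, sh))
  }
  invisible(path)
}

#' Write per-unit results as a TSV table
#'
#' Tab-separated with header, one row per unit, floats at 17 significant
#' digits so the table round-trips through [read_unit_table()] exactly.
#'
#' @param results a data frame (or list of one-row records sharing a
#'   schema).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_unit_table <- function(results, path) {
  if (!is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  df <- results
  if (is.null(df)) df <- data.frame()
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-unit TSV table written by [write_unit_table()]
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_unit_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
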