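#' @name pipeline
#' @title Session and cohort orchestration
#'
#' @description
#' [run_session()] sequences the full per-session pipeline -- kinematics,
#' theta detection, and per-unit speed, theta-locking and autocorrelogram
#' analyses -- into one per-unit result table, deterministic under a fixed
#' seed. [summarize_cohort()] aggregates unit tables into per-group counts
#' and fractions of p-/n-Speed cells with exact (Clopper-Pearson) binomial
#' intervals plus group means and SDs.
NULL

#' Default analysis configuration
#'
#' Every tunable of the pipeline with its standard value: 25.6-ms bins,
#' 512-ms Gaussian smoothing, 2-50 cm/s walking band, 100 circular shuffles
#' with a 30-s margin, +/-1536-ms temporal-shift window, 5-11 Hz theta
#' band with power-ratio threshold 2, 5-ms theta-index ACG bins, 1-ms
#' feature ACG bins.
#'
#' @param ... overrides of any default field.
#' @return a named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(dt = 0.0256, sd = 0.512, vmin = 2, vmax = 50,
              n_shuffles = 100, margin = 30, max_shift = 1.536,
              min_bins = 100, theta_band = c(5, 11), ratio_thresh = 2,
              theta_min_dur = 1, acg_bin_theta = 0.005, acg_bin = 0.001,
              min_spikes_theta = 100, min_spikes_acg = 200,
              smooth_width = 0.2816, max_gap = 1, seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the per-session analysis pipeline
#'
#' Kinematics (interpolation, local-regression position smoothing, speed),
#' theta-epoch detection on the reference LFP channel, then for each unit
#' the full speed profile ([speed_cell_analysis()]), theta-phase statistics,
#' theta index and autocorrelogram features. Speed-cell classes are
#' assigned from the pooled shuffle distribution of the session's units.
#' Every unit appears exactly once in the output; units failing a stage
#' floor keep their row with `NA` in the affected columns and the reason in
#' the exclusion log (`attr(result, "exclusions")`).
#'
#' @param session a [session_bundle()].
#' @param config an [analysis_config()].
#' @param theta_ref name of the LFP channel used as theta reference
#'   (default the first channel).
#' @return data frame, one row per unit, with attributes `exclusions`
#'   (data frame of unit/stage/reason), `thresholds` (pooled 1st/99th
#'   percentile speed-score thresholds), and `config`.
#' @export
run_session <- function(session, config = analysis_config(),
                        theta_ref = NULL) {
  stopifnot(inherits(session, "session_bundle"))
  dur <- session$duration
  pos <- interpolate_position(session$trajectory, dt = config$dt,
                              duration = dur, max_gap = config$max_gap)
  xs <- smooth_position(pos$x, width = config$smooth_width)
  ys <- smooth_position(pos$y, width = config$smooth_width)
  speed <- compute_speed(xs, ys, sd = config$sd, vmin = config$vmin,
                         vmax = config$vmax)
  lfp <- NULL; epochs <- NULL
  if (length(session$lfp)) {
    theta_ref <- theta_ref %||% names(session$lfp)[1]
    lfp <- session$lfp[[theta_ref]]
    epochs <- detect_theta_epochs(lfp, ratio_thresh = config$ratio_thresh,
                                  min_dur = config$theta_min_dur,
                                  theta_band = config$theta_band)
  }
  excl <- list()
  note <- function(unit, stage, reason)
    excl[[length(excl) + 1L]] <<- data.frame(unit_id = unit, stage = stage,
                                             reason = reason)
  rows <- vector("list", length(session$units))
  fits <- vector("list", length(session$units))
  for (k in seq_along(session$units)) {
    u <- session$units[[k]]
    fit <- speed_cell_analysis(u$spike_times, speed, dur,
                               dt = config$dt, sd = config$sd,
                               n_shuffles = config$n_shuffles,
                               margin = config$margin,
                               max_shift = config$max_shift,
                               min_bins = config$min_bins,
                               seed = unit_seed(config$seed, k))
    fits[[k]] <- fit
    if (is.na(fit$speed_score))
      note(u$unit_id, "speed", "undefined speed score (too few valid bins or zero variance)")
    if (isTRUE(fit$shift_excluded))
      note(u$unit_id, "shift", "preferred shift at lag-window boundary")
    pp <- NA_real_; R <- NA_real_; nph <- 0L
    if (!is.null(lfp)) {
      ph <- spike_theta_phase(lfp, epochs, u$spike_times, speed = speed,
                              band = config$theta_band)
      cs <- circular_stats(ph)
      pp <- cs$preferred_phase; R <- cs$R; nph <- cs$n
    }
    st_theta <- if (!is.null(epochs)) {
      keep <- in_epochs(u$spike_times, epochs)
      b <- as.integer(floor(u$spike_times / config$dt)) + 1L
      ok <- b >= 1L & b <= length(speed$values)
      keep <- keep & ok
      keep[keep] <- speed$valid[b[keep]]
      u$spike_times[keep]
    } else u$spike_times
    ti <- theta_index(st_theta, acg_bin = config$acg_bin_theta,
                      min_spikes = config$min_spikes_theta)
    if (is.na(ti$theta_index))
      note(u$unit_id, "theta_index", "too few theta-epoch spikes")
    af <- acg_features(u$spike_times, bin = config$acg_bin,
                       min_spikes = config$min_spikes_acg)
    if (is.na(af$burst_index))
      note(u$unit_id, "acg", "too few spikes for ACG features")
    rows[[k]] <- data.frame(
      unit_id = u$unit_id, region_layer = u$region_layer %||% NA_character_,
      n_spikes = length(u$spike_times), mean_rate = fit$mean_rate,
      speed_score = fit$speed_score, slope = fit$slope,
      norm_slope = fit$norm_slope, info_per_spike = fit$info_per_spike,
      info_per_sec = fit$info_per_sec,
      preferred_shift = fit$preferred_shift,
      shift_excluded = isTRUE(fit$shift_excluded),
      preferred_phase = pp, resultant_length = R, n_phase_spikes = nph,
      theta_index = ti$theta_index, theta_modulated = ti$theta_modulated,
      burst_index = af$burst_index, refractory_ms = af$refractory_ms)
  }
  res <- do.call(rbind, rows)
  cls <- classify_speed_cells(res$speed_score,
                              lapply(fits, `[[`, "null_scores"))
  res$cell_class <- cls$class
  attr(res, "thresholds") <- cls$thresholds
  attr(res, "exclusions") <- if (length(excl)) do.call(rbind, excl)
  else data.frame(unit_id = character(0), stage = character(0),
                  reason = character(0))
  attr(res, "config") <- config
  attr(res, "null_scores") <- lapply(fits, `[[`, "null_scores")
  res
}

#' Cohort-level summary of unit tables
#'
#' Counts and fractions of p-Speed and n-Speed cells per group with exact
#' 95% Clopper-Pearson confidence intervals (via `binom.test`), group means
#' and SDs of score, slope, normalised slope, information and preferred
#' shift, and optionally between-group tests: Fisher's exact test on the
#' p-Speed fractions and one-way ANOVA with Bonferroni-corrected pairwise
#' t-tests on the speed scores.
#'
#' @param units a unit table from [run_session()] (or several
#'   `rbind`-ed).
#' @param group name of the grouping column (default `"region_layer"`).
#' @param tests run between-group tests when more than one group is present
#'   (default `TRUE`).
#' @return data frame of class `cohort_summary`, one row per group, with
#'   attribute `tests` (list with `fisher_p`, `anova_p`,
#'   `pairwise_p_bonferroni`) when computed.
#' @export
summarize_cohort <- function(units, group = "region_layer", tests = TRUE) {
  g <- units[[group]]
  keep <- !is.na(g)
  units <- units[keep, , drop = FALSE]; g <- g[keep]
  groups <- unique(g)
  rows <- lapply(groups, function(gr) {
    d <- units[g == gr, , drop = FALSE]
    n <- nrow(d)
    if (n == 0L) return(NULL)
    np <- sum(d$cell_class == "p-Speed", na.rm = TRUE)
    nn <- sum(d$cell_class == "n-Speed", na.rm = TRUE)
    cip <- stats::binom.test(np, n)$conf.int
    cin <- stats::binom.test(nn, n)$conf.int
    msd <- function(v) c(mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE))
    sc <- msd(d$speed_score); sl <- msd(d$slope); ns <- msd(d$norm_slope)
    ips <- msd(d$info_per_spike); is2 <- msd(d$info_per_sec)
    sh <- msd(d$preferred_shift)
    data.frame(group = gr, n = n,
               n_pspeed = np, frac_pspeed = np / n,
               pspeed_ci_lo = cip[1], pspeed_ci_hi = cip[2],
               n_nspeed = nn, frac_nspeed = nn / n,
               nspeed_ci_lo = cin[1], nspeed_ci_hi = cin[2],
               score_mean = sc[1], score_sd = sc[2],
               slope_mean = sl[1], slope_sd = sl[2],
               norm_slope_mean = ns[1], norm_slope_sd = ns[2],
               info_spike_mean = ips[1], info_spike_sd = ips[2],
               info_sec_mean = is2[1], info_sec_sd = is2[2],
               shift_mean = sh[1], shift_sd = sh[2],
               rate_score_cor = safe_cor(d$mean_rate[!is.na(d$speed_score)],
                                         d$speed_score[!is.na(d$speed_score)]))
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) warning("empty group(s) omitted: ",
                          paste(groups[empty], collapse = ", "))
  out <- do.call(rbind, rows[!empty])
  if (tests && length(unique(out$group)) > 1L) {
    tab <- cbind(out$n_pspeed, out$n - out$n_pspeed)
    fp <- tryCatch(stats::fisher.test(tab)$p.value, error = function(e) NA_real_)
    av <- tryCatch(summary(stats::aov(speed_score ~ grp,
                                      data = data.frame(speed_score = units$speed_score,
                                                        grp = factor(g))))[[1]][["Pr(>F)"]][1],
                   error = function(e) NA_real_)
    pw <- tryCatch(stats::pairwise.t.test(units$speed_score, factor(g),
                                          p.adjust.method = "bonferroni")$p.value,
                   error = function(e) NULL)
    attr(out, "tests") <- list(fisher_p = fp, anova_p = av,
                               pairwise_p_bonferroni = pw)
  }
  class(out) <- c("cohort_summary", "data.frame")
  out
}
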