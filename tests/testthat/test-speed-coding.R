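mk_series <- function(v, valid = NULL) binned_series(v, dt = 0.0256, valid = valid)

test_that("instantaneous rate conserves spike count before masking", {
  set.seed(1)
  st <- sort(runif(3000, 0, 600))
  r <- instantaneous_rate(st, 600, sd = 0)
  expect_equal(sum(r$values) * r$dt, length(st))
  rs <- instantaneous_rate(st, 600)
  expect_equal(mean(rs$values), length(st) / 600, tolerance = 1e-3)
  expect_equal(instantaneous_rate(numeric(0), 100)$values,
               rep(0, floor(100 / 0.0256)))
})

test_that("a regular train smooths to its rate everywhere in the interior", {
  st <- seq(0.05, 600, by = 0.1)
  r <- instantaneous_rate(st, 600)
  interior <- 200:23000
  expect_equal(r$values[interior], rep(10, length(interior)), tolerance = 0.1)
})

test_that("speed score equals the textbook Pearson correlation", {
  kin <- shared_kin()
  st <- simulate_unit(unit_truth(baseline_rate = 5, speed_gain = 0.5),
                      kin$traj, duration = kin$duration, seed = 77)
  rate <- instantaneous_rate(st, kin$duration)
  sc <- speed_score(rate, kin$speed)
  use <- rate$valid & kin$speed$valid
  expect_equal(sc, cor(rate$values[use], kin$speed$values[use]),
               tolerance = 1e-12)
  # perfect linear relations
  v <- kin$speed
  expect_equal(speed_score(mk_series(v$values, v$valid), v), 1)
  expect_equal(speed_score(mk_series(-v$values + 60, v$valid), v), -1)
})

test_that("speed score is invariant under affine rescaling of the rate", {
  kin <- shared_kin()
  st <- simulate_unit(unit_truth(baseline_rate = 5, speed_gain = 0.3),
                      kin$traj, duration = kin$duration, seed = 78)
  rate <- instantaneous_rate(st, kin$duration)
  rate2 <- mk_series(3.5 * rate$values + 1.2, rate$valid)
  expect_equal(speed_score(rate2, kin$speed), speed_score(rate, kin$speed),
               tolerance = 1e-12)
})

test_that("degenerate series yield flagged (NA) scores, not zeros", {
  v <- mk_series(rep(10, 5000))
  const <- mk_series(rep(3, 5000))
  expect_true(is.na(speed_score(const, v)))
  short <- mk_series(rnorm(50))
  expect_true(is.na(speed_score(short, mk_series(rnorm(50)))))
})

test_that("speed slope matches the closed-form OLS oracle", {
  kin <- shared_kin()
  v <- kin$speed
  rate <- mk_series(2 + 0.5 * v$values, v$valid)
  sl <- speed_slope(rate, v)
  expect_equal(sl$slope, 0.5, tolerance = 1e-12)
  expect_equal(sl$norm_slope, 0.5 / sl$mean_rate, tolerance = 1e-12)
  # noisy unit against cov/var computed directly
  st <- simulate_unit(unit_truth(baseline_rate = 5, speed_gain = 0.25),
                      kin$traj, duration = kin$duration, seed = 79)
  r2 <- instantaneous_rate(st, kin$duration)
  use <- r2$valid & v$valid
  expect_equal(speed_slope(r2, v)$slope,
               cov(r2$values[use], v$values[use]) / var(v$values[use]),
               tolerance = 1e-12)
  # constant rate: zero slope
  expect_equal(speed_slope(mk_series(rep(4, length(v$values)), v$valid), v)$slope,
               0, tolerance = 1e-12)
})

test_that("speed information reproduces closed forms and the summation oracle", {
  # two bins, p = (.5, .5), lambda = (0, 2): 1 bit/spike and 1 bit/s
  info <- skaggs_information(c(0.5, 0.5), c(0, 2), 1)
  expect_equal(info$per_spike, 1)
  expect_equal(info$per_sec, 1)
  # flat tuning carries no information
  expect_equal(skaggs_information(rep(0.25, 4), rep(3, 4), 3)$per_spike, 0)
  # information is non-negative and the per-sec identity is exact
  set.seed(9)
  for (i in 1:20) {
    p <- runif(12); p <- p / sum(p)
    lam <- runif(12, 0, 10)
    lb <- sum(p * lam)
    r <- skaggs_information(p, lam, lb)
    oracle <- sum(ifelse(p * lam > 0, p * (lam / lb) * log2(lam / lb), 0))
    expect_equal(r$per_spike, oracle, tolerance = 1e-12)
    expect_equal(r$per_sec, lb * r$per_spike, tolerance = 1e-12)
    expect_gte(r$per_spike, -1e-12)
  }
  expect_true(is.na(skaggs_information(1, 0, 0)$per_spike))
})

test_that("the speed tuning curve uses 4 cm/s bins on [2, 50]", {
  kin <- shared_kin()
  st <- simulate_unit(unit_truth(baseline_rate = 5, speed_gain = 0.5),
                      kin$traj, duration = kin$duration, seed = 80)
  rate <- instantaneous_rate(st, kin$duration)
  si <- speed_information(rate, kin$speed)
  expect_lte(nrow(si$tuning), 12)
  expect_true(all(si$tuning$hi - si$tuning$lo == 4))
  expect_true(all(si$tuning$lo >= 2 & si$tuning$hi <= 50))
  expect_equal(sum(si$tuning$p), 1, tolerance = 1e-12)
  expect_equal(si$per_sec, attr(si$tuning, "mean_rate") * si$per_spike,
               tolerance = 1e-12)
  expect_gt(si$per_spike, 0)
})

test_that("the temporal-shift curve shares its zero-lag value with the score", {
  kin <- shared_kin()
  st <- simulate_unit(unit_truth(baseline_rate = 5, speed_gain = 0.5),
                      kin$traj, duration = kin$duration, seed = 81)
  rate <- instantaneous_rate(st, kin$duration)
  ts <- temporal_shift_curve(rate, kin$speed)
  expect_length(ts$r, 121)
  expect_identical(ts$r[ts$tau == 0], speed_score(rate, kin$speed))
  expect_equal(ts$normalized[ts$tau == 0], 1)
  # rate == speed peaks at zero lag with r = 1
  ts0 <- temporal_shift_curve(mk_series(kin$speed$values, kin$speed$valid),
                              kin$speed)
  expect_equal(ts0$preferred_shift, 0)
  expect_equal(max(ts0$r), 1)
})

test_that("lags beyond the window produce a boundary exclusion", {
  kin <- shared_kin()
  st <- simulate_unit(unit_truth(baseline_rate = 5, speed_gain = 0.5,
                                 speed_lag = 2.0),
                      kin$traj, duration = kin$duration, seed = 82)
  rate <- instantaneous_rate(st, kin$duration)
  ts <- temporal_shift_curve(rate, kin$speed)
  expect_true(ts$excluded)
  expect_true(is.na(ts$preferred_shift))
})

test_that("circular shuffles preserve spike count and are seed-reproducible", {
  kin <- shared_kin()
  st <- simulate_unit(unit_truth(baseline_rate = 5, speed_gain = 0.3),
                      kin$traj, duration = kin$duration, seed = 83)
  # the surrogate transform preserves the spike count and circular ISIs
  set.seed(1); s <- runif(1, 30, kin$duration - 30)
  sh <- sort((st + s) %% kin$duration)
  expect_length(sh, length(st))
  isi <- function(x) sort(diff(c(x, x[1] + kin$duration)))
  expect_equal(isi(sh), isi(sort(st)), tolerance = 1e-9)
  n1 <- shuffle_null(st, kin$speed, kin$duration, n = 20, seed = 99)
  n2 <- shuffle_null(st, kin$speed, kin$duration, n = 20, seed = 99)
  expect_identical(n1, n2)
  expect_error(shuffle_null(st, kin$speed, 50), "too short")
})

test_that("for an unmodulated unit the observed score sits inside its null", {
  kin <- shared_kin()
  st <- simulate_unit(unit_truth(baseline_rate = 8, speed_gain = 0),
                      kin$traj, duration = kin$duration, seed = 84)
  rate <- instantaneous_rate(st, kin$duration)
  obs <- speed_score(rate, kin$speed)
  nulls <- shuffle_null(st, kin$speed, kin$duration, n = 60, seed = 5)
  expect_lt(abs(obs - mean(nulls)), 2 * sd(nulls))
})

test_that("speed-cell classification uses strict pooled-percentile rules", {
  nulls <- list(seq(-0.05, 0.05, length.out = 100),
                seq(-0.05, 0.05, length.out = 100))
  cls <- classify_speed_cells(c(0.2, -0.2, 0, NA), nulls)
  expect_equal(as.character(cls$class),
               c("p-Speed", "n-Speed", "non-speed", NA))
  # exactly at the threshold is NOT a speed cell (strict inequality)
  thr <- cls$thresholds
  at <- classify_speed_cells(c(thr[2], thr[1]), nulls)
  expect_equal(as.character(at$class), c("non-speed", "non-speed"))
  # per-cell mode thresholds each cell against its own null
  pc <- classify_speed_cells(c(0.2, 0.2), list(rep(0, 100), seq(0, 0.5, length.out = 100)),
                             pooled = FALSE)
  expect_equal(as.character(pc$class), c("p-Speed", "non-speed"))
})

test_that("the per-cell analysis object carries a coherent summary", {
  kin <- shared_kin()
  st <- simulate_unit(unit_truth(baseline_rate = 5, speed_gain = 0.5),
                      kin$traj, duration = kin$duration, seed = 85)
  fit <- speed_cell_analysis(st, kin$speed, kin$duration, n_shuffles = 10,
                             seed = 3)
  expect_s3_class(fit, "speed_cell_fit")
  expect_equal(fit$info_per_sec,
               attr(fit$tuning, "mean_rate") * fit$info_per_spike,
               tolerance = 1e-10)
  expect_identical(fit$shift$r[fit$shift$tau == 0], fit$speed_score)
  expect_equal(unname(coef(fit)["speed_score"]), fit$speed_score)
  s <- summary(fit)
  expect_equal(s$slope, fit$slope)
  expect_output(print(fit), "speed score")
})
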