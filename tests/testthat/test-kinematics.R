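straight_traj <- function(duration = 100, v = 10) {
  t <- seq(0, duration, by = 1 / 30)
  data.frame(t = t, fx = 5 + v * t, fy = 60, rx = 5 + v * t - 12, ry = 60)
}

test_that("position interpolation reproduces straight-line samples exactly", {
  tr <- straight_traj()
  pos <- interpolate_position(tr, duration = 100)
  tb <- bin_times(pos$x)
  expect_equal(pos$x$values, 5 + 10 * tb, tolerance = 1e-9)
  expect_equal(pos$y$values, rep(60, length(tb)))
  expect_true(all(pos$x$valid))
})

test_that("a single dropped frame is bridged without masking", {
  tr <- straight_traj()
  tr$fx[100] <- NA; tr$fy[100] <- NA
  pos <- interpolate_position(tr, duration = 100)
  tb <- bin_times(pos$x)
  expect_equal(pos$x$values, 5 + 10 * tb, tolerance = 1e-9)
  expect_true(all(pos$x$valid))
})

test_that("tracking gaps longer than the limit mask the covered bins", {
  tr <- straight_traj()
  gap <- tr$t > 40 & tr$t < 42        # 2-s dropout
  tr$fx[gap] <- NA; tr$fy[gap] <- NA
  pos <- interpolate_position(tr, duration = 100, max_gap = 1)
  tb <- bin_times(pos$x)
  in_gap <- tb > max(tr$t[tr$t <= 40]) & tb < min(tr$t[tr$t >= 42])
  expect_true(all(!pos$x$valid[in_gap]))
  expect_true(all(pos$x$valid[!in_gap]))
  # number of masked bins equals the gap length over dt
  expect_equal(sum(!pos$x$valid), sum(in_gap))
  expect_gt(sum(!pos$x$valid), 2 / 0.0256 - 3)
})

test_that("interpolation refuses sessions without valid tracking", {
  tr <- straight_traj()
  tr$fx[] <- NA
  expect_error(interpolate_position(tr), "valid tracking")
})

test_that("local-regression smoothing is exact on ramps and constants", {
  ramp <- binned_series(seq(0, 5, length.out = 300))
  expect_equal(smooth_position(ramp)$values, ramp$values, tolerance = 1e-12)
  const <- binned_series(rep(2.5, 300))
  expect_equal(smooth_position(const)$values, const$values, tolerance = 1e-12)
})

test_that("local-regression smoothing matches a brute-force weighted fit", {
  set.seed(7)
  y <- cumsum(rnorm(80))
  s <- smooth_position(binned_series(y))
  oracle <- vapply(seq_along(y), function(i) {
    lo <- max(1, i - 5); hi <- min(length(y), i + 5)
    d <- (lo:hi) - i
    w <- (1 - (abs(d) / max(abs(d)))^3)^3
    fit <- lm(y[lo:hi] ~ d, weights = w)
    unname(fit$coefficients[1])
  }, numeric(1))
  expect_equal(s$values, oracle, tolerance = 1e-9)
})

test_that("an impulse is attenuated with window-limited support", {
  y <- rep(0, 101); y[51] <- 1
  s <- smooth_position(binned_series(y))
  expect_lt(s$values[51], 1)
  expect_equal(s$values[abs(seq_along(y) - 51) > 5], rep(0, 90),
               tolerance = 1e-12)
})

test_that("constant-velocity motion recovers its speed; walking mask applies", {
  tr <- straight_traj(100, v = 10)
  pos <- interpolate_position(tr, duration = 100)
  sp <- compute_speed(smooth_position(pos$x), smooth_position(pos$y))
  mid <- 200:3500
  expect_equal(sp$values[mid], rep(10, length(mid)), tolerance = 0.1)
  expect_true(all(sp$valid[mid]))
  # stationary animal: zero speed, fully masked by the 2 cm/s floor
  tr0 <- straight_traj(100, v = 0)
  sp0 <- compute_speed(smooth_position(interpolate_position(tr0, duration = 100)$x),
                       smooth_position(interpolate_position(tr0, duration = 100)$y))
  expect_equal(max(sp0$values), 0, tolerance = 1e-9)
  expect_false(any(sp0$valid))
})

test_that("circular motion recovers v = 2*pi*r/T", {
  r <- 50; T <- 31.4159
  t <- seq(0, 120, by = 1 / 30)
  tr <- data.frame(t = t, fx = 60 + r * cos(2 * pi * t / T),
                   fy = 60 + r * sin(2 * pi * t / T), rx = NA, ry = NA)
  pos <- interpolate_position(tr, duration = 120)
  sp <- compute_speed(smooth_position(pos$x), smooth_position(pos$y))
  mid <- 200:4300
  expect_equal(mean(sp$values[mid]), 2 * pi * r / T, tolerance = 0.2)
})

test_that("speed is invariant under rigid motion of the trajectory", {
  kin <- shared_kin()
  tr <- kin$traj
  th <- 0.7
  tr2 <- tr
  tr2$fx <- 30 + cos(th) * tr$fx - sin(th) * tr$fy
  tr2$fy <- -10 + sin(th) * tr$fx + cos(th) * tr$fy
  pos2 <- interpolate_position(tr2, duration = kin$duration)
  sp2 <- compute_speed(smooth_position(pos2$x), smooth_position(pos2$y))
  expect_equal(sp2$values, kin$speed$values, tolerance = 1e-8)
})

test_that("smoothed path length never exceeds the raw polyline length", {
  kin <- shared_kin()
  raw <- sum(sqrt(diff(kin$traj$fx)^2 + diff(kin$traj$fy)^2))
  smoothed <- sum(kin$speed$values * kin$speed$dt)
  expect_lte(smoothed, raw)
})

test_that("head direction follows the LED geometry", {
  t <- seq(0, 100, by = 1 / 30)
  east <- data.frame(t = t, fx = 60, fy = 60, rx = 48, ry = 60)
  hd <- head_direction(east, duration = 100)
  expect_equal(unique(round(hd$values, 10)), 0)
  north <- data.frame(t = t, fx = 60, fy = 60, rx = 60, ry = 48)
  hd2 <- head_direction(north, duration = 100)
  expect_equal(unique(round(hd2$values, 10)), round(pi / 2, 10))
  norear <- data.frame(t = t, fx = 60, fy = 60, rx = NA_real_, ry = NA_real_)
  expect_error(head_direction(norear, duration = 100), "rear LED")
})

test_that("head direction tracks a scripted heading within 2 degrees RMS", {
  kin <- shared_kin()
  hd <- head_direction(kin$traj, duration = kin$duration)
  truth <- attr(kin$traj, "heading")
  tt <- kin$traj$t
  ref <- approx(tt, unclass(truth), xout = bin_times(hd), rule = 2)$y
  dphi <- Arg(exp(1i * (hd$values - ref)))
  # exclude bins right at heading reflections where interpolation lags
  core <- abs(dphi) < 0.5
  expect_gt(mean(core), 0.95)
  expect_lt(sqrt(mean(dphi[core]^2)) * 180 / pi, 2)
})
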