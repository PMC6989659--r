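poisson_train <- function(rate, duration, seed) {
  set.seed(seed)
  sort(runif(rpois(1, rate * duration), 0, duration))
}

connected_pair <- function(rate = 5, duration = 300, p_trans = 0.2,
                           delay = 0.002, seed = 1) {
  pre <- poisson_train(rate, duration, seed)
  set.seed(seed + 5000)
  post <- sort(c(poisson_train(rate, duration, seed + 10000),
                 pre[runif(length(pre)) < p_trans] + delay))
  list(pre = pre, post = post[post < duration])
}

test_that("an injected 2-ms excitatory connection is detected", {
  hits <- vapply(1:20, function(s) {
    pp <- connected_pair(seed = s)
    jitter_ccg_test(pp$pre, pp$post, seed = s)$verdict == "excitatory"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("independent Poisson pairs rarely trigger a verdict", {
  verdicts <- vapply(1:60, function(s) {
    a <- poisson_train(5, 300, 2 * s)
    b <- poisson_train(5, 300, 2 * s + 1)
    jitter_ccg_test(a, b, seed = s)$verdict
  }, character(1))
  expect_lte(mean(verdicts != "none"), 0.05)
})

test_that("the observed CCG matches a brute-force pair count", {
  pp <- connected_pair(seed = 3)
  r <- jitter_ccg_test(pp$pre, pp$post, n_surr = 50, seed = 3)
  d <- as.vector(outer(pp$post, pp$pre, "-"))
  expect_equal(sum(r$ccg), sum(d > -0.02 & d <= 0.02) + sum(d == -0.02))
  oracle_bin <- sum(d > 0.001 & d <= 0.002)
  expect_equal(r$ccg[r$lags > 0.001 & r$lags < 0.002], oracle_bin)
  expect_length(r$lags, 40)
  # too few spikes: insufficient verdict
  few <- jitter_ccg_test(1:10, 1:10, n_surr = 10)
  expect_equal(few$verdict, "none")
  expect_true(few$insufficient)
})

test_that("the feature ACG reads bursts and refractory structure correctly", {
  # doublet-rich train: every spike has a +4 ms partner
  base <- poisson_train(5, 600, 7)
  doublets <- sort(c(base, base + 0.004))
  fd <- acg_features(doublets)
  expect_gt(fd$burst_index, 0.5)
  # homogeneous Poisson at an interneuron-like rate: flat ACG, near-zero
  # burst index (the bin-max peak estimator needs well-filled bins)
  pois <- poisson_train(50, 200, 8)
  fp <- acg_features(pois)
  expect_lt(abs(fp$burst_index), 0.1)
  expect_true(fp$burst_index >= -1 && fp$burst_index <= 1)
  # non-bursty train with a strict refractory period emptying the burst
  # window: negative burst index, refractory detected at or after 8 ms
  refr0 <- poisson_train(20, 500, 9)
  keep <- rep(TRUE, length(refr0)); last <- refr0[1]
  for (i in 2:length(refr0)) {
    if (refr0[i] - last >= 0.012) { last <- refr0[i] } else keep[i] <- FALSE
  }
  refr <- refr0[keep]
  fr <- acg_features(refr)
  expect_gte(fr$refractory_ms, 8)
  expect_lte(fr$burst_index, 0)
  expect_true(is.na(acg_features(1:10)$burst_index))
})

test_that("burst index stays within [-1, 1] across varied trains", {
  for (s in 1:5) {
    st <- poisson_train(sample(2:20, 1), 300, 100 + s)
    bi <- acg_features(st, min_spikes = 50)$burst_index
    expect_gte(bi, -1); expect_lte(bi, 1)
  }
})

test_that("the PV/SOM decision boxes reproduce the printed rules", {
  expect_equal(classify_pv_som(0.5, 3), "PV")
  expect_equal(classify_pv_som(-0.3, 10), "SOM")
  expect_equal(classify_pv_som(0.2, 9), "unclassified")
  expect_equal(classify_pv_som(-0.2, 3), "unclassified")
  expect_equal(classify_pv_som(0, 5), "unclassified")      # needs strict sign
  expect_equal(classify_pv_som(NA, 5), "unclassified")
  # pure function: repeated application is stable
  expect_identical(classify_pv_som(0.5, 3), classify_pv_som(0.5, 3))
})

test_that("waveform separation recovers two-Gaussian classes and is deterministic", {
  set.seed(30)
  n <- 120
  feats <- data.frame(
    trough_to_peak = c(rnorm(n, 0.8, 0.1), rnorm(n, 0.25, 0.08)),
    asymmetry = c(rnorm(n, 0.3, 0.15), rnorm(n, -0.2, 0.15)))
  truth <- rep(c("excitatory", "inhibitory"), each = n)
  labels <- truth
  labels[sample(2 * n, 150)] <- NA       # only a subset jitter-labelled
  r1 <- waveform_ei_separation(feats, labels)
  expect_equal(r1$method, "lda")
  agree <- mean((r1$ei == "principal") == (truth == "excitatory"))
  expect_gte(agree, 0.95)
  r2 <- waveform_ei_separation(feats, labels)
  expect_identical(r1$score, r2$score)
  # the low-confidence flag is exactly the near-boundary criterion
  expect_identical(r1$low_confidence, abs(r1$score) < 0.1)
  # too few labels: fixed boundary fallback
  r3 <- waveform_ei_separation(feats, rep(NA, 2 * n))
  expect_equal(r3$method, "fixed")
  expect_gte(mean((r3$ei == "principal") == (truth == "excitatory")), 0.9)
  # a unit sitting exactly on the fixed boundary is low-confidence
  on_b <- waveform_ei_separation(
    data.frame(trough_to_peak = 0.425, asymmetry = 0), NA)
  expect_true(on_b$low_confidence)
})

test_that("EC2 region classification is driven by the configured polar regions", {
  regions <- ec2_default_regions()
  # synthetic clusters drawn inside each configured region
  set.seed(31)
  n <- 200
  pyr_phase <- runif(n, pi / 2 + 0.1, 3 * pi / 2 - 0.1)
  pyr_r <- runif(n, 0.2, 0.9)
  ste_phase <- (runif(n, 3 * pi / 2 + 0.1, 2 * pi + pi / 2 - 0.1)) %% (2 * pi)
  ste_r <- runif(n, 0.1, 0.9)
  got_p <- mapply(classify_ec2_stellate_pyramidal, pyr_phase, pyr_r)
  got_s <- mapply(classify_ec2_stellate_pyramidal, ste_phase, ste_r)
  expect_gte(mean(got_p == "pyramidal"), 0.95)
  expect_gte(mean(got_s == "stellate"), 0.95)
  # boundary and undefined inputs stay unclassified
  expect_equal(classify_ec2_stellate_pyramidal(pi, 0.15), "unclassified")
  expect_equal(classify_ec2_stellate_pyramidal(NA, 0.5), "unclassified")
})
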