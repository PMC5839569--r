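test_that("fast autocorrelation equals the brute-force definition", {
  set.seed(101)
  for (i in 1:20) {
    N <- sample(16:256, 1)
    w <- rnorm(N)
    fast <- normalizedAutocorrelation(w, 100)
    expect_lt(max(abs(fast$values - bruteAcf(w))), 1e-10)
  }
  # and on structured signals
  w <- sin(2 * pi * 8 * (0:127) / 128) + rnorm(128, sd = 0.1)
  expect_lt(max(abs(normalizedAutocorrelation(w, 128)$values -
                    bruteAcf(w))), 1e-10)
})

test_that("autocorrelation is normalised, bounded and scale invariant", {
  set.seed(5)
  w <- rnorm(512)
  acf <- normalizedAutocorrelation(w, 512)
  expect_equal(acf$values[1], 1)
  expect_true(all(abs(acf$values) <= 1 + 1e-9))
  acf2 <- normalizedAutocorrelation(-3.7 * w, 512)
  expect_lt(max(abs(acf$values - acf2$values)), 1e-10)
  expect_error(normalizedAutocorrelation(rep(1, 64), 64), "degenerate")
  expect_error(normalizedAutocorrelation(rnorm(4), 64), "short")
})

test_that("a periodic window shows its period as the dominant lag", {
  fs <- 1024
  w <- cos(2 * pi * 8 * (0:(fs - 1)) / fs)  # period 128 samples
  acf <- normalizedAutocorrelation(w, fs)
  band <- 64:192
  peak <- band[which.max(acf$values[band + 1])]
  # the biased estimator attenuates by (1 - k/N), so the sample peak may
  # sit one sample inside the true period
  expect_lte(abs(peak - 128), 1)
  expect_gt(acf$values[129], 0.95 * max(acf$values[band + 1]))
})

test_that("white-noise autocorrelation obeys the large-N null bound", {
  set.seed(77)
  N <- 1024
  hits <- vapply(1:1000, function(i) {
    acf <- normalizedAutocorrelation(rnorm(N), N)
    max(abs(acf$values[-1])) < 4 / sqrt(N)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("local maxima extraction anchors at (0,1) and keeps strict peaks", {
  acf <- list(values = c(1, 0.5, 0.8, 0.3, 0.6, 0.1), fs = 1)
  pts <- acfLocalMaxima(acf, maxLag = 5)
  expect_equal(pts$lag_s, c(0, 2, 4))
  expect_equal(pts$value, c(1, 0.8, 0.6))
  # strictly decreasing sequence: anchor only
  mono <- list(values = seq(1, 0, length.out = 20), fs = 1)
  expect_equal(nrow(acfLocalMaxima(mono)), 1)
  # negative maxima are discarded
  neg <- list(values = c(1, -0.5, -0.2, -0.8, 0.1, 0.4, 0.05), fs = 1)
  expect_true(all(acfLocalMaxima(neg, maxLag = 6)$value > 0))
})

test_that("damped-cosine maxima lie on the analytic envelope", {
  fs <- 1024
  tau0 <- 0.15   # decay slow relative to the 10 Hz period, so the
                 # sampled maxima sit close to the envelope touch points
  lag <- 0:511
  vals <- exp(-lag / (fs * tau0)) * cos(2 * pi * 10 * lag / fs)
  pts <- acfLocalMaxima(list(values = vals, fs = fs), maxLag = 400)
  interior <- pts[pts$lag_s > 0, ]
  expect_gt(nrow(interior), 2)
  expect_lt(max(abs(interior$value / exp(-interior$lag_s / tau0) - 1)),
            0.02)
})

test_that("relaxation fit recovers an exact exponential", {
  t <- c(0, 0.05, 0.1, 0.2, 0.4)
  fit <- fitRelaxation(data.frame(lag_s = t, value = exp(-t / 0.2)))
  expect_true(fit$valid)
  expect_equal(fit$C, 1)
  expect_equal(fit$tau, 0.2, tolerance = 1e-6 / 0.2)
  expect_gt(fit$rSquared, 0.9999)
  # fewer than 3 points is an invalid fit, not an error
  short <- fitRelaxation(data.frame(lag_s = c(0, 0.1), value = c(1, 0.5)))
  expect_false(short$valid)
})

test_that("fit agrees with a dense grid-search oracle on noisy points", {
  set.seed(12)
  grid <- exp(seq(log(1e-4), log(10), length.out = 1e5))
  for (i in 1:5) {
    tau0 <- runif(1, 0.05, 0.5)
    t <- seq(0, 0.5, by = 0.1)
    y <- exp(-t / tau0) + rnorm(length(t), sd = 0.02)
    fit <- fitRelaxation(data.frame(lag_s = t, value = y))
    sse <- colSums((exp(-outer(t, 1 / grid)) - y)^2)
    expect_equal(fit$tau, grid[which.min(sse)], tolerance = 1e-4)
  }
})

test_that("fitted tau is scale invariant and monotone in the pole radius", {
  set.seed(31)
  w <- arWindows(0.99, 1, fs = 1024, seed = 31)[, 1]
  f1 <- fitWindowTau(w, 1024)
  f2 <- fitWindowTau(5.5 * w, 1024)
  expect_equal(f1$tau, f2$tau, tolerance = 1e-9)
  meds <- vapply(c(0.95, 0.97, 0.99, 0.995), medianFittedTau, numeric(1),
                 nWindows = 60, seed = 13)
  expect_true(all(diff(meds) > 0))
})

test_that("tau time courses show the intention effect and flag bad trials", {
  tau <- defaultTauRun(1)$tau
  expect_true(all(is.na(tau$tau_s[!tau$valid])))
  expect_true(all(is.finite(tau$tau_s[tau$valid])))
  # movement tau in the intention window exceeds pre-onset tau per trial
  ch <- "C3-P3"
  move <- tau[tau$condition == "right" & tau$channel == ch & tau$valid, ]
  perTrial <- vapply(split(move, move$trial), function(d) {
    mean(d$tau_s[d$window_end_time_s >= 0 & d$window_end_time_s <= 1]) -
      mean(d$tau_s[d$window_end_time_s >= -2 & d$window_end_time_s <= -1])
  }, numeric(1))
  # one-sided sign test
  expect_lt(binom.test(sum(perTrial > 0), length(perTrial),
                       alternative = "greater")$p.value, 0.05)
  # constant-zero trial: every window invalid, trial flagged
  ep <- array(0, dim = c(1, 1, 6 * 256))
  zero <- new("TrialSet", epochs = ep,
              timeAxis = (seq_len(6 * 256) - 1 - 3 * 256) / 256,
              condition = "rest", fs = 256, channelLabels = "C3-P3")
  expect_warning(tz <- tauTimecourse(zero, NULL, NULL,
                                     spec = windowSpec()), "flagged")
  expect_true(all(!tz$valid))
  expect_true(all(!tz$trial_valid))
})

test_that("grand averages ignore invalid windows and degenerate to the
           input for replicated series", {
  base <- data.frame(condition = "right", trial = 1, channel = "C3-P3",
                     band = "wide",
                     window_end_time_s = seq(-2, 3, by = 0.1),
                     tau_s = seq(0.1, 0.2, length.out = 51),
                     r_squared = 0.9, valid = TRUE, trial_valid = TRUE)
  rep10 <- do.call(rbind, lapply(1:10, function(i) {
    b <- base; b$trial <- i; b
  }))
  ga <- grandAverageTau(rep10)
  expect_equal(ga$mean_tau_s, base$tau_s)
  expect_equal(ga$sd_tau_s, rep(0, 51))
  expect_equal(ga$n, rep(10, 51))
  # one all-invalid series in a group of 5 drops out of the counts
  rep5 <- do.call(rbind, lapply(1:5, function(i) {
    b <- base; b$trial <- i
    if (i == 5) { b$valid <- FALSE; b$trial_valid <- FALSE }
    b
  }))
  ga5 <- grandAverageTau(rep5)
  expect_equal(ga5$n, rep(4, 51))
  expect_error(grandAverageTau(base[base$valid == FALSE, ]), "empty-set")
})
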