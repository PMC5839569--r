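test_that("perfectly separated classes reach sensitivity 1", {
  set.seed(1)
  v <- c(rnorm(40, 10, 0.1), rnorm(40, 0, 0.1))
  lab <- rep(c(TRUE, FALSE), each = 40)
  cv <- cvSensitivity(v, lab, cvScheme(seed = 1))
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$sd, 0)
  expect_equal(cv$nTap, 40)
})

test_that("null features stay near chance and below the threshold", {
  thr <- binomialThreshold(40)
  sens <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    v <- rnorm(80)
    cvSensitivity(v, rep(c(TRUE, FALSE), each = 40),
                  cvScheme(seed = i))$sensitivity
  }, numeric(1))
  expect_gte(mean(sens >= 0.35 & sens <= 0.65), 0.9)
  expect_gte(mean(sens < thr), 0.9)
})

test_that("the discriminant equals the midpoint rule and MASS::lda", {
  set.seed(9)
  for (i in 1:100) {
    xt <- rnorm(20, runif(1, 0, 2)); xr <- rnorm(20)
    xs <- rnorm(15, 0.5)
    pred <- relaxEEG:::ldaPredictTap(xt, xr, xs)
    mid <- (mean(xt) + mean(xr)) / 2
    predMid <- if (mean(xt) > mean(xr)) xs > mid else xs < mid
    expect_identical(pred, predMid)
  }
  # independent reference implementation, equal priors
  set.seed(10)
  xt <- rnorm(20, 1); xr <- rnorm(20); xs <- rnorm(50, 0.5)
  fit <- MASS::lda(x = data.frame(v = c(xt, xr)),
                   grouping = factor(rep(c("tap", "rest"), each = 20)),
                   prior = c(0.5, 0.5))
  ref <- predict(fit, data.frame(v = xs))$class == "tap"
  expect_identical(relaxEEG:::ldaPredictTap(xt, xr, xs), unname(ref))
})

test_that("sensitivity is invariant under order-preserving transforms", {
  set.seed(22)
  v <- c(rnorm(40, 1.2), rnorm(40))
  lab <- rep(c(TRUE, FALSE), each = 40)
  s0 <- cvSensitivity(v, lab, cvScheme(seed = 3))$sensitivity
  # affine maps leave the discriminant decisions identical
  s1 <- cvSensitivity(2.5 * v + 7, lab, cvScheme(seed = 3))$sensitivity
  expect_equal(s0, s1)
  s2 <- cvSensitivity(-1 * v, lab, cvScheme(seed = 3))$sensitivity
  expect_equal(s0, s2)
  # a mild nonlinear monotone transform stays within Monte-Carlo slack
  s3 <- cvSensitivity(sign(v) * abs(v)^1.2, lab,
                      cvScheme(seed = 3))$sensitivity
  expect_lt(abs(s0 - s3), 0.05)
})

test_that("the binomial chance threshold matches the exact tail sum", {
  # independent oracle: accumulate the Binomial(n, 1/2) upper tail
  oracle <- function(n, alpha = 0.05) {
    for (k in 0:n)
      if (sum(stats::dbinom(k:n, n, 0.5)) <= alpha) return(k / n)
    1
  }
  expect_equal(binomialThreshold(40), 26 / 40)
  expect_equal(binomialThreshold(40), oracle(40))
  for (n in c(10, 20, 40, 55, 80, 160))
    expect_equal(binomialThreshold(n), oracle(n))
  expect_equal(binomialThreshold(40, 1), 0)
  thr <- vapply(c(20, 40, 80, 160), binomialThreshold, numeric(1))
  expect_true(all(diff(thr) <= 0))
  expect_error(binomialThreshold(8), "configuration")
})

test_that("curves are deterministic and flat for uninformative features", {
  grid <- seq(-1, 1, by = 0.5)
  feats <- do.call(rbind, lapply(grid, function(t0)
    data.frame(channel = "C3-P3", window_end_time_s = t0,
               trial = 1:40, value = 1,
               is_tap = rep(c(TRUE, FALSE), 20))))
  c1 <- sensitivityCurve(feats, cvScheme(seed = 5))
  c2 <- sensitivityCurve(feats, cvScheme(seed = 5))
  expect_identical(c1, c2)
  expect_true(all(abs(c1$sensitivity - 0.5) <= 0.15))
})

test_that("detection timing reads first crossing and peak off the grid", {
  curve <- data.frame(channel = "Cz-Pz",
                      end_time_s = c(-1, -0.5, 0, 0.5),
                      sensitivity = c(0.5, 0.6, 0.7, 0.8), sd = 0,
                      n_tap = 40, n_rest = 40)
  d <- detectTiming(curve, 0.65)
  expect_equal(d$first_crossing_time, 0)
  expect_equal(d$peak_sensitivity, 0.8)
  expect_equal(d$peak_time, 0.5)
  d2 <- detectTiming(curve, 0.95)
  expect_true(is.na(d2$first_crossing_time))
  expect_equal(d2$peak_sensitivity, 0.8)
})

test_that("channel selection prefers the informative channel and breaks
           ties by order", {
  set.seed(3)
  mkFeats <- function(ch, effect, seed) {
    do.call(rbind, lapply(seq(-1, 1, by = 0.25), function(t0) {
      v <- rnorm(60)
      if (effect && t0 >= -0.25 && t0 <= 0.75) v[1:30] <- v[1:30] + 2.5
      data.frame(channel = ch, window_end_time_s = t0, trial = 1:60,
                 value = v, is_tap = rep(c(TRUE, FALSE), each = 30))
    }))
  }
  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    feats <- rbind(mkFeats("good", TRUE), mkFeats("n1", FALSE),
                   mkFeats("n2", FALSE), mkFeats("n3", FALSE),
                   mkFeats("n4", FALSE), mkFeats("n5", FALSE))
    curves <- sensitivityCurve(feats, cvScheme(seed = seed))
    selectBestChannel(curves, binomialThreshold(30))$best_channel == "good"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # exact tie: first channel in order wins
  curve <- data.frame(channel = rep(c("a", "b"), each = 2),
                      end_time_s = rep(c(0, 1), 2),
                      sensitivity = rep(c(0.7, 0.9), 2), sd = 0,
                      n_tap = 40, n_rest = 40)
  expect_equal(selectBestChannel(curve, 0.65)$best_channel, "a")
  expect_error(selectBestChannel(curve[0, ], 0.65), "empty-set")
})
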