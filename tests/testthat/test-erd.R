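test_that("power envelope tracks squared amplitude", {
  fs <- 1024
  t <- seq_len(4 * fs) / fs
  core <- fs:(3 * fs)
  s <- sin(2 * pi * 10 * t)
  up <- powerEnvelope(s, "upper")
  expect_true(all(up >= 0))
  expect_lt(max(abs(up[core] - 1)), 0.02)
  both <- powerEnvelope(s, "mean_of_both")
  expect_lt(abs(mean(both[core]) - 0.5), 0.02)
  # slowly amplitude-modulated tone: envelope follows a(t)^2
  a <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  env <- powerEnvelope(a * s, "upper")
  expect_lt(max(abs(env[core] / a[core]^2 - 1)), 0.05)
  # degenerate input passes through with a note
  expect_message(z <- powerEnvelope(rep(0, 100)), "extrema")
  expect_equal(z, rep(0, 100))
})

test_that("ERD percentage follows its defining arithmetic", {
  expect_equal(erdPercent(1, 1), 0)
  expect_equal(erdPercent(2, 1), 100)
  expect_equal(erdPercent(0.25, 1), -75)
  expect_error(erdPercent(1, 0), "baseline")
})

test_that("single-trial ERD obeys the quadratic amplitude law", {
  for (a in c(0.9, 0.7, 0.5)) {
    cfg <- synthConfig(fs = 256, nTrialsPerCondition = 10,
                       conditions = c("right", "rest"),
                       channelLabels = c("C3", "P3"), arGain = 0,
                       noiseSd = 0, muAmp = 1, erdScale = a, seed = 21)
    ses <- generateSession(cfg)
    trials <- epochTrials(toBipolar(ses$recording,
      bipolarScheme(cbind("C3", "P3"))), ses$events)
    erd <- singleTrialErd(trials, 8, 13)
    plateau <- erd[erd$condition == "right" &
                   erd$window_end_time_s >= 0.5 &
                   erd$window_end_time_s <= 1, ]
    expect_lt(abs(mean(plateau$erd_percent) - (a^2 - 1) * 100), 8)
    # rest trials hover around zero
    rest <- erd[erd$condition == "rest", ]
    expect_lt(abs(mean(rest$erd_percent)), 10)
  }
})

test_that("ERD is invariant under global amplitude scaling", {
  s <- smallSession(seed = 14, nPer = 4, fs = 256)
  erd1 <- singleTrialErd(s$trials, 8, 13)
  scaled <- new("TrialSet", epochs = trialEpochs(s$trials) * 7,
                timeAxis = timeAxis(s$trials),
                condition = trialConditions(s$trials),
                fs = samplingRate(s$trials),
                channelLabels = channelLabels(s$trials))
  erd2 <- singleTrialErd(scaled, 8, 13)
  # exact in exact arithmetic; the recursive filter chain leaves
  # floating-point noise at the 1e-8 relative level
  expect_equal(erd1$erd_percent, erd2$erd_percent, tolerance = 1e-7)
  ga1 <- grandAverageErd(s$trials, 8, 13)
  ga2 <- grandAverageErd(scaled, 8, 13)
  expect_equal(ga1$erd_percent, ga2$erd_percent, tolerance = 1e-7)
})

test_that("null ERD contrast vanishes when the mu amplitude is unchanged", {
  s <- smallSession(seed = 16, nPer = 12, fs = 256, erdScale = 1,
                    rhoMove = 0.99)
  erd <- singleTrialErd(s$trials, 8, 13)
  # per-trial means: overlapping windows are correlated within a trial
  perTrial <- aggregate(erd_percent ~ trial + condition, erd, mean)
  move <- perTrial$erd_percent[perTrial$condition == "right"]
  rest <- perTrial$erd_percent[perTrial$condition == "rest"]
  expect_gt(t.test(move, rest)$p.value, 0.05)
})

test_that("grand-average ERD dips after onset in a mu-prominent session", {
  # mu-dominant fixture: at 256 Hz the narrowband background contributes
  # large chi-square noise to 8-13 Hz power, so it is scaled down to
  # isolate the mu attenuation this test is about
  cfg <- synthConfig(fs = 256, nTrialsPerCondition = 12,
                     conditions = c("right", "rest"), muAmp = 1.5,
                     arGain = 0.3,
                     channelLabels = c("C3", "Cz", "P3", "Pz"), seed = 33)
  ses <- generateSession(cfg)
  trials <- epochTrials(toBipolar(applyFilters(ses$recording),
    bipolarScheme(cbind(c("C3", "Cz"), c("P3", "Pz")))), ses$events)
  ga <- grandAverageErd(trials, 8, 13)
  post <- ga[ga$condition == "right" & ga$window_end_time_s >= 0.25 &
             ga$window_end_time_s <= 1, ]
  rest <- ga[ga$condition == "rest", ]
  expect_lt(mean(post$erd_percent), -20)
  expect_lt(abs(mean(rest$erd_percent)), 10)
  # identical trials leave no residual variance after evoked removal
  ep <- trialEpochs(trials)
  ep[2, , ] <- ep[1, , ]
  twin <- new("TrialSet", epochs = ep[1:2, , , drop = FALSE],
              timeAxis = timeAxis(trials),
              condition = c("rest", "rest"), fs = samplingRate(trials),
              channelLabels = channelLabels(trials))
  expect_error(grandAverageErd(twin, 8, 13), "degenerate-variance")
  single <- new("TrialSet", epochs = ep[1, , , drop = FALSE],
                timeAxis = timeAxis(trials), condition = "rest",
                fs = samplingRate(trials),
                channelLabels = channelLabels(trials))
  expect_error(grandAverageErd(single, 8, 13), "empty-set")
})

test_that("spectral perturbation map localises the mu-band power loss", {
  cfg <- synthConfig(fs = 256, nTrialsPerCondition = 10,
                     conditions = c("right", "rest"), muAmp = 1.5,
                     arGain = 0.5, channelLabels = c("C3", "P3"),
                     seed = 41)
  ses <- generateSession(cfg)
  trials <- epochTrials(toBipolar(ses$recording,
    bipolarScheme(cbind("C3", "P3"))), ses$events)
  em <- erspMap(trials)
  expect_true(min(em$freqs) >= 0.5 && max(em$freqs) <= 60)
  expect_gt(max(em$times), 2)
  expect_lt(min(em$times), -2)
  tile <- em$values[em$freqs >= 8 & em$freqs <= 13,
                    em$times >= 0 & em$times <= 1]
  pre <- em$values[em$freqs >= 8 & em$freqs <= 13,
                   em$times >= -2.5 & em$times <= -1]
  expect_lt(mean(tile), mean(pre) - 1)  # at least 1 dB deeper after onset
  expect_lt(mean(tile), 0)
  # self-subtraction gives an all-zero map
  ep <- trialEpochs(trials)
  half <- ep[1:4, , , drop = FALSE]
  dup <- new("TrialSet", epochs = half[c(1, 2, 1, 2), , , drop = FALSE],
             timeAxis = timeAxis(trials),
             condition = c("right", "right", "rest", "rest"),
             fs = samplingRate(trials),
             channelLabels = channelLabels(trials))
  em0 <- erspMap(dup)
  expect_lt(max(abs(em0$values)), 1e-9)
  expect_error(erspMap(trials, moveCondition = "left"), "empty-set")
})
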