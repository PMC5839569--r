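# AR(2) coefficients for poles at rho * exp(+-i 2 pi fOsc / fs):
# x_t = a1 x_{t-1} + a2 x_{t-2} + e_t with a1 = 2 rho cos(theta), a2 = -rho^2.
arCoefficients <- function(rho, fOsc, fs) {
  theta <- 2 * pi * fOsc / fs
  c(a1 = 2 * rho * cos(theta), a2 = -rho^2)
}

# stationary variance of the AR(2) process with unit-variance innovations
ar2StationaryVariance <- function(rho, fOsc, fs) {
  a <- arCoefficients(rho, fOsc, fs)
  a1 <- a[["a1"]]; a2 <- a[["a2"]]
  (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
}

#' Closed-form relaxation time of an AR(2) autocorrelation envelope
#'
#' For an AR(2) process with pole radius `rho`, the autocorrelation at lag
#' k has envelope `rho^k`; writing `rho^k = exp(-k / (fs * tau))` gives the
#' e-folding time `tau = -1 / (fs * log(rho))` in seconds. This is the
#' ground truth against which fitted relaxation times from synthetic
#' sessions are validated.
#'
#' @param rho AR pole radius, strictly between 0 and 1.
#' @param fs sampling rate (Hz).
#' @return the relaxation time in seconds.
#' @examples
#' theoreticalTau(0.99, 1024)   # ~0.0972 s
#' theoreticalTau(0.995, 1024)  # ~0.1948 s
#' @export
theoreticalTau <- function(rho, fs) {
  if (any(rho <= 0) || any(rho >= 1))
    stop("rho must be strictly inside (0, 1)")
  if (any(fs <= 0)) stop("fs must be positive")
  -1 / (fs * log(rho))
}

#' Configure a synthetic EEG session
#'
#' Defaults reproduce the study conditions the generator emulates: 1024 Hz,
#' the nine motor-area 10-20 channels, 40 trials per condition, 6 s epochs,
#' a ~10 Hz rhythm on a broadband AR(2) background, movement trials with
#' the pole radius raised from 0.99 to 0.995 inside `[-0.5, +1]` s around
#' the tap and the mu amplitude halved after onset.
#'
#' @param fs sampling rate (Hz).
#' @param channelLabels ordered channel labels.
#' @param nTrialsPerCondition trials per condition.
#' @param conditions which conditions to simulate.
#' @param epochSpan seconds before / after onset.
#' @param rhoRest,rhoMove AR pole radius at rest / during intention.
#' @param fOsc AR(2) resonance frequency (Hz).
#' @param intentionInterval `[start, end]` s relative to onset.
#' @param erdScale mu-amplitude multiplier during `[0, +1]` s (ramp from
#'   -0.5 s).
#' @param muAmp mu-oscillation amplitude relative to the unit-variance
#'   background.
#' @param arGain gain of the AR(2) background (0 gives a background-free
#'   mu fixture).
#' @param noiseSd additive white measurement-noise sd.
#' @param mixing shared-source mixing coefficient in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return a validated [SynthConfig-class] object.
#' @export
synthConfig <- function(fs = 1024,
                        channelLabels = c("F3", "Fz", "F4", "C3", "Cz",
                                          "C4", "P3", "Pz", "P4"),
                        nTrialsPerCondition = 40,
                        conditions = c("right", "left", "rest"),
                        epochSpan = c(3, 3),
                        rhoRest = 0.99, rhoMove = 0.995, fOsc = 10,
                        intentionInterval = c(-0.5, 1),
                        erdScale = 0.5, muAmp = 0.5, arGain = 1,
                        noiseSd = 0.1, mixing = 0, seed = 1L) {
  if (rhoRest >= 1 || rhoMove >= 1)
    stop("AR pole radius >= 1: process unstable")
  new("SynthConfig", fs = fs, channelLabels = channelLabels,
      nTrialsPerCondition = as.integer(nTrialsPerCondition),
      conditions = conditions, epochSpan = as.numeric(epochSpan),
      rhoRest = rhoRest, rhoMove = rhoMove, fOsc = fOsc,
      intentionInterval = as.numeric(intentionInterval),
      erdScale = erdScale, muAmp = muAmp, arGain = arGain,
      noiseSd = noiseSd, mixing = mixing, seed = as.integer(seed))
}

# piecewise AR(2) filtering with state carried across rho segments.
# segments: data.frame(from, to, rho) covering 1..n contiguously.
# Innovations are rescaled per segment so the stationary variance stays 1
# regardless of rho: the pole switch changes the decay of temporal
# dependence without a power confound.
piecewiseAR2 <- function(innov, segments, fOsc, fs) {
  out <- numeric(length(innov))
  state <- c(0, 0)  # (x_{t-1}, x_{t-2})
  for (i in seq_len(nrow(segments))) {
    idx <- segments$from[i]:segments$to[i]
    rho <- segments$rho[i]
    a <- arCoefficients(rho, fOsc, fs)
    sdScale <- 1 / sqrt(ar2StationaryVariance(rho, fOsc, fs))
    seg <- stats::filter(innov[idx] * sdScale, a, method = "recursive",
                         init = state)
    out[idx] <- seg
    n <- length(seg)
    state <- c(seg[n], if (n > 1) seg[n - 1] else state[1])
  }
  out
}

# mu amplitude envelope over the whole recording: 1 at rest; in movement
# trials ramps to erdScale over [-0.5, 0] s, holds over [0, +1] s, and
# recovers to 1 over [+1, +1.5] s.
muEnvelope <- function(n, fs, onsets, labels, erdScale) {
  env <- rep(1, n)
  if (erdScale == 1) return(env)
  for (k in seq_along(onsets)) {
    if (labels[k] == "rest") next
    o <- onsets[k]
    rampIn <- o + seq.int(round(-0.5 * fs), -1L)
    hold <- o + seq.int(0L, round(1 * fs) - 1L)
    rampOut <- o + seq.int(round(1 * fs), round(1.5 * fs) - 1L)
    env[rampIn[rampIn >= 1 & rampIn <= n]] <-
      seq(1, erdScale, length.out = length(rampIn))[rampIn >= 1 & rampIn <= n]
    env[hold[hold >= 1 & hold <= n]] <- erdScale
    env[rampOut[rampOut >= 1 & rampOut <= n]] <-
      seq(erdScale, 1, length.out = length(rampOut))[rampOut >= 1 &
                                                     rampOut <= n]
  }
  env
}

#' Generate a synthetic EEG session with known ground truth
#'
#' Builds a continuous multichannel recording plus its tap-event list.
#' Each channel is an independent AR(2) process (resonance `fOsc`, pole
#' radius `rhoRest`) whose pole radius switches to `rhoMove` inside the
#' intention interval of movement trials, with the AR state carried across
#' the switch so the signal itself is continuous. A mu-band sinusoid with
#' per-channel random phase rides on the background and is attenuated by
#' `erdScale` after movement onset. Condition order is randomised and
#' inter-trial gaps are drawn uniformly from 1 to 1.5 s. Identical
#' configurations (including seed) give bit-identical output.
#'
#' @param config a [synthConfig()] object.
#' @return a list with elements `recording` ([EEGRecording-class]) and
#'   `events` ([EventList-class]).
#' @examples
#' cfg <- synthConfig(nTrialsPerCondition = 2, conditions = c("right", "rest"),
#'                    fs = 256, channelLabels = c("C3", "P3"))
#' ses <- generateSession(cfg)
#' ses$recording
#' @export
generateSession <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  arGain <- config@arGain
  fs <- config@fs
  pre <- config@epochSpan[1]; post <- config@epochSpan[2]
  nch <- length(config@channelLabels)

  set.seed(config@seed)
  labels <- sample(rep(config@conditions, config@nTrialsPerCondition))
  ntr <- length(labels)
  gaps <- runif(ntr, 1.0, 1.5)

  # lay out onsets: margin, epoch, gap, epoch, ...
  onsetsSec <- numeric(ntr)
  cursor <- 0.5  # lead-in margin before the first epoch
  for (k in seq_len(ntr)) {
    onsetsSec[k] <- cursor + pre
    cursor <- onsetsSec[k] + post + gaps[k]
  }
  n <- ceiling((cursor + 0.5) * fs)
  onsets <- round(onsetsSec * fs) + 1L

  # rho segments shared by all channels
  bounds <- integer(0)
  for (k in seq_len(ntr)) {
    if (labels[k] == "rest") next
    from <- onsets[k] + round(config@intentionInterval[1] * fs)
    to <- onsets[k] + round(config@intentionInterval[2] * fs) - 1L
    bounds <- rbind(bounds, c(max(1L, from), min(n, to)))
  }
  segStart <- 1L; segments <- NULL
  if (length(bounds)) {
    for (i in seq_len(nrow(bounds))) {
      if (bounds[i, 1] > segStart)
        segments <- rbind(segments,
                          data.frame(from = segStart, to = bounds[i, 1] - 1L,
                                     rho = config@rhoRest))
      segments <- rbind(segments,
                        data.frame(from = bounds[i, 1], to = bounds[i, 2],
                                   rho = config@rhoMove))
      segStart <- bounds[i, 2] + 1L
    }
  }
  if (segStart <= n)
    segments <- rbind(segments, data.frame(from = segStart, to = n,
                                           rho = config@rhoRest))

  env <- muEnvelope(n, fs, onsets, labels, config@erdScale)
  tt <- seq_len(n) / fs

  sig <- matrix(0, nch, n)
  shared <- if (config@mixing > 0)
    piecewiseAR2(rnorm(n), segments, config@fOsc, fs)
  else NULL
  # mu-phase segments: one random phase per trial per channel, switching
  # at the midpoints of the inter-trial gaps so no epoch contains a
  # phase discontinuity
  cuts <- if (ntr > 1)
    round((onsets[-ntr] + diff(onsets) / 2))
  else integer(0)
  segFrom <- c(1L, cuts)
  segTo <- c(cuts - 1L, n)
  for (ch in seq_len(nch)) {
    bg <- if (arGain > 0)
      arGain * piecewiseAR2(rnorm(n), segments, config@fOsc, fs)
    else { rnorm(n); numeric(n) }  # burn the draw to keep streams aligned
    phases <- runif(length(segFrom), 0, 2 * pi)
    mu <- numeric(n)
    for (k in seq_along(segFrom)) {
      idx <- segFrom[k]:segTo[k]
      mu[idx] <- sin(2 * pi * config@fOsc * tt[idx] + phases[k])
    }
    mu <- config@muAmp * env * mu
    noise <- if (config@noiseSd > 0) rnorm(n, sd = config@noiseSd)
             else numeric(n)
    sig[ch, ] <- bg + mu + noise
  }
  if (!is.null(shared))
    sig <- (1 - config@mixing) * sig +
      config@mixing * matrix(shared, nch, n, byrow = TRUE)

  rec <- EEGRecording(sig, fs, config@channelLabels)
  ev <- EventList(onsets, labels, fs)
  list(recording = rec, events = ev)
}
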