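#' @import methods
#' @importFrom stats aggregate approx fft filter mvfft nextn optimize
#'   pbinom pnorm qbinom rnorm runif sd t.test var
NULL

#' Continuous multichannel EEG recording
#'
#' A channels-by-time matrix of EEG samples (microvolts) together with its
#' sampling rate and ordered channel labels. This is the container returned
#' by [generateSession()] and [loadRecording()] and consumed by the whole
#' preprocessing chain.
#'
#' @slot samples numeric matrix, channels in rows, samples in columns (uV).
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one label per row of `samples`.
#'
#' @seealso [applyFilters()], [toBipolar()], [epochTrials()]
#' @export
setClass("EEGRecording",
  representation(samples = "matrix", fs = "numeric",
                 channelLabels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (nrow(object@samples) != length(object@channelLabels))
      msg <- c(msg, "channelLabels length must equal the number of rows")
    if (anyDuplicated(toupper(object@channelLabels)))
      msg <- c(msg, "duplicate channel labels")
    if (length(object@samples) && !all(is.finite(object@samples)))
      msg <- c(msg, "samples contain non-finite values")
    if (length(msg)) msg else TRUE
  })

#' Tap-onset event list
#'
#' Sample indices of tap onsets (1-based, strictly increasing) with the
#' condition performed at each: `"right"`, `"left"` or `"rest"`. For rest
#' trials the onset is only the epoch alignment point.
#'
#' @slot onsets integer vector of onset sample indices.
#' @slot labels character vector of conditions, one per onset.
#' @slot fs sampling rate (Hz) the indices refer to.
#' @export
setClass("EventList",
  representation(onsets = "integer", labels = "character", fs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@onsets) != length(object@labels))
      msg <- c(msg, "onsets and labels must have equal length")
    if (is.unsorted(object@onsets, strictly = TRUE))
      msg <- c(msg, "onsets must be strictly increasing")
    if (!all(object@labels %in% c("right", "left", "rest")))
      msg <- c(msg, "labels must be 'right', 'left' or 'rest'")
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Condition-labelled epochs time-locked to tap onset
#'
#' A trials x channels x samples array covering a fixed span around each
#' tap onset (default 3 s before to 3 s after). Every epoch is demeaned per
#' channel so downstream autocorrelation and band-power estimates see
#' zero-mean signals.
#'
#' @slot epochs numeric array `trial x channel x sample`.
#' @slot timeAxis numeric vector of times (s), onset at 0.
#' @slot condition character vector of per-trial conditions.
#' @slot fs sampling rate (Hz).
#' @slot channelLabels channel names (referential or bipolar).
#' @export
setClass("TrialSet",
  representation(epochs = "array", timeAxis = "numeric",
                 condition = "character", fs = "numeric",
                 channelLabels = "character"),
  validity = function(object) {
    d <- dim(object@epochs)
    msg <- character()
    if (length(d) != 3L)
      msg <- c(msg, "epochs must be a 3-D array (trial x channel x sample)")
    else {
      if (d[1] != length(object@condition))
        msg <- c(msg, "condition length must equal trial count")
      if (d[2] != length(object@channelLabels))
        msg <- c(msg, "channelLabels length must equal channel count")
      if (d[3] != length(object@timeAxis))
        msg <- c(msg, "timeAxis length must equal sample count")
    }
    if (!all(object@condition %in% c("right", "left", "rest")))
      msg <- c(msg, "conditions must be 'right', 'left' or 'rest'")
    if (length(msg)) msg else TRUE
  })

#' Synthetic-session configuration
#'
#' Parameters of the synthetic EEG generator. Each channel is an AR(2)
#' process with resonance `fOsc` whose pole radius is `rhoRest` except,
#' inside movement epochs, `rhoMove` during the intention interval; a
#' mu-band oscillatory component of amplitude `muAmp` is attenuated by
#' `erdScale` after onset (ramped in from -0.5 s); white measurement noise
#' of sd `noiseSd` is added.
#'
#' @slot fs sampling rate (Hz).
#' @slot channelLabels ordered channel labels.
#' @slot nTrialsPerCondition trials per condition.
#' @slot conditions conditions to simulate.
#' @slot epochSpan seconds before / after onset.
#' @slot rhoRest,rhoMove AR pole radii (0 < rhoRest <= rhoMove < 1).
#' @slot fOsc AR(2) resonance frequency (Hz).
#' @slot intentionInterval `[start, end]` s relative to onset during which
#'   the pole radius is `rhoMove` in movement trials.
#' @slot erdScale mu-amplitude multiplier during `[0, +1]` s of movement
#'   trials (ramped from -0.5 s).
#' @slot muAmp amplitude of the mu oscillation (uV), in units of the
#'   unit-variance AR background.
#' @slot noiseSd additive white noise sd (uV).
#' @slot mixing shared-source mixing coefficient across channels (0 = fully
#'   independent channels).
#' @slot seed integer RNG seed; identical seed gives bit-identical output.
#' @export
setClass("SynthConfig",
  representation(fs = "numeric", channelLabels = "character",
                 nTrialsPerCondition = "integer", conditions = "character",
                 epochSpan = "numeric", rhoRest = "numeric",
                 rhoMove = "numeric", fOsc = "numeric",
                 intentionInterval = "numeric", erdScale = "numeric",
                 muAmp = "numeric", arGain = "numeric", noiseSd = "numeric",
                 mixing = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@rhoRest > 0 && object@rhoRest <= object@rhoMove &&
          object@rhoMove < 1))
      msg <- c(msg, "need 0 < rhoRest <= rhoMove < 1")
    if (object@fs <= 2 * object@fOsc)
      msg <- c(msg, "fs must exceed 2 * fOsc")
    if (length(object@epochSpan) != 2L || any(object@epochSpan <= 0))
      msg <- c(msg, "epochSpan must be two positive durations")
    ii <- object@intentionInterval
    if (length(ii) != 2L || ii[1] >= ii[2] ||
        ii[1] < -object@epochSpan[1] || ii[2] > object@epochSpan[2])
      msg <- c(msg, "intentionInterval must lie inside the epoch span")
    if (!all(object@conditions %in% c("right", "left", "rest")))
      msg <- c(msg, "conditions must be among 'right', 'left', 'rest'")
    if (object@nTrialsPerCondition < 1L)
      msg <- c(msg, "nTrialsPerCondition must be >= 1")
    if (object@erdScale < 0) msg <- c(msg, "erdScale must be >= 0")
    if (object@arGain < 0) msg <- c(msg, "arGain must be >= 0")
    if (object@mixing < 0 || object@mixing >= 1)
      msg <- c(msg, "mixing must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channel(s) x %d samples (%.1f s at %g Hz)\n",
              nrow(object@samples), ncol(object@samples),
              ncol(object@samples) / object@fs, object@fs))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
})

setMethod("show", "EventList", function(object) {
  cat(sprintf("EventList: %d event(s) at %g Hz\n",
              length(object@onsets), object@fs))
  if (length(object@labels))
    print(table(factor(object@labels, c("right", "left", "rest"))))
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf(
    "TrialSet: %d trial(s) x %d channel(s) x %d samples at %g Hz\n",
    d[1], d[2], d[3], object@fs))
  cat(sprintf("  time axis [%.3f, %.3f] s; conditions: %s\n",
              min(object@timeAxis), max(object@timeAxis),
              paste(sprintf("%s=%d", names(table(object@condition)),
                            table(object@condition)), collapse = ", ")))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: fs=%g Hz, %d channel(s), %d trials x {%s}\n",
    object@fs, length(object@channelLabels), object@nTrialsPerCondition,
    paste(object@conditions, collapse = ", ")))
  cat(sprintf(
    "  rho %g -> %g in [%g, %g] s; fOsc=%g Hz; erdScale=%g; muAmp=%g; seed=%d\n",
    object@rhoRest, object@rhoMove, object@intentionInterval[1],
    object@intentionInterval[2], object@fOsc, object@erdScale, object@muAmp,
    object@seed))
})

# ---- accessors ----

#' @rdname EEGRecording-class
#' @param object an object of the documented class.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname TrialSet-class
#' @param object a `TrialSet`.
#' @export
setMethod("samplingRate", "TrialSet", function(object) object@fs)
#' @rdname EventList-class
#' @param object an `EventList`.
#' @export
setMethod("samplingRate", "EventList", function(object) object@fs)

#' @rdname EEGRecording-class
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname EEGRecording-class
#' @export
setMethod("channelLabels", "EEGRecording",
          function(object) object@channelLabels)
#' @rdname TrialSet-class
#' @export
setMethod("channelLabels", "TrialSet", function(object) object@channelLabels)

#' @rdname EEGRecording-class
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname EEGRecording-class
#' @export
setMethod("signalMatrix", "EEGRecording", function(object) object@samples)

#' @rdname EventList-class
#' @export
setGeneric("eventOnsets", function(object) standardGeneric("eventOnsets"))
#' @rdname EventList-class
#' @export
setMethod("eventOnsets", "EventList", function(object) object@onsets)

#' @rdname EventList-class
#' @export
setGeneric("eventLabels", function(object) standardGeneric("eventLabels"))
#' @rdname EventList-class
#' @export
setMethod("eventLabels", "EventList", function(object) object@labels)

#' @rdname TrialSet-class
#' @export
setGeneric("trialEpochs", function(object) standardGeneric("trialEpochs"))
#' @rdname TrialSet-class
#' @export
setMethod("trialEpochs", "TrialSet", function(object) object@epochs)

#' @rdname TrialSet-class
#' @export
setGeneric("trialConditions", function(object)
  standardGeneric("trialConditions"))
#' @rdname TrialSet-class
#' @export
setMethod("trialConditions", "TrialSet", function(object) object@condition)

#' @rdname TrialSet-class
#' @export
setGeneric("timeAxis", function(object) standardGeneric("timeAxis"))
#' @rdname TrialSet-class
#' @export
setMethod("timeAxis", "TrialSet", function(object) object@timeAxis)

#' @rdname TrialSet-class
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname TrialSet-class
#' @export
setMethod("nTrials", "TrialSet", function(object) dim(object@epochs)[1])

#' Construct an EEGRecording
#'
#' @param samples channels x time numeric matrix (uV).
#' @param fs sampling rate (Hz).
#' @param channelLabels one label per channel; defaults to rownames.
#' @return an [EEGRecording-class] object.
#' @export
EEGRecording <- function(samples, fs,
                         channelLabels = rownames(samples)) {
  if (is.null(channelLabels))
    stop("channelLabels required when samples has no rownames")
  samples <- as.matrix(samples)
  rownames(samples) <- channelLabels
  new("EEGRecording", samples = samples, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels))
}

#' Construct an EventList
#'
#' @param onsets 1-based onset sample indices, strictly increasing.
#' @param labels condition per onset (`right`, `left` or `rest`).
#' @param fs sampling rate (Hz).
#' @return an [EventList-class] object.
#' @export
EventList <- function(onsets, labels, fs) {
  new("EventList", onsets = as.integer(onsets),
      labels = as.character(labels), fs = as.numeric(fs))
}
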