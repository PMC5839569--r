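#' Standard frequency bands
#'
#' The four analysis bands: low (0.5-8 Hz), mu (8-13 Hz), beta (13-30 Hz)
#' and the wide band (0.5-30 Hz).
#'
#' @return a data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
standardBands <- function() {
  data.frame(name = c("low", "mu", "beta", "wide"),
             lo = c(0.5, 8, 13, 0.5),
             hi = c(8, 13, 30, 30))
}

#' Longitudinal bipolar montage over the motor area
#'
#' @param pairs two-column character matrix (anode, cathode); the default
#'   is the six motor-area derivations F3-C3, Fz-Cz, F4-C4, C3-P3, Cz-Pz,
#'   C4-P4.
#' @return a data.frame with columns `anode`, `cathode`, `name`.
#' @export
bipolarScheme <- function(pairs = cbind(
    c("F3", "Fz", "F4", "C3", "Cz", "C4"),
    c("C3", "Cz", "C4", "P3", "Pz", "P4"))) {
  data.frame(anode = pairs[, 1], cathode = pairs[, 2],
             name = paste0(pairs[, 1], "-", pairs[, 2]))
}

# forward-backward filtering with odd-reflection padding so that edge
# transients (severe for the 0.5 Hz high-pass) land in the pads
zeroPhase <- function(filt, x, padSec = 3, fs = NULL) {
  n <- length(x)
  npad <- if (is.null(fs)) min(n - 1L, 3072L)
          else min(n - 1L, round(padSec * fs))
  if (npad < 1) return(signal::filtfilt(filt, x))
  head <- 2 * x[1] - x[(npad + 1):2]
  tail <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(filt, c(head, x, tail))
  y[(npad + 1):(npad + n)]
}

#' Apply the standard filtering chain
#'
#' High-pass at 0.5 Hz (DC / drift removal), band-stop 48-52 Hz (50 Hz
#' line-noise notch) and low-pass at 60 Hz, each a 4th-order Butterworth
#' design applied forward-backward for zero phase. The per-channel mean is
#' subtracted afterwards.
#'
#' @param rec an [EEGRecording-class]; its sampling rate must exceed
#'   120 Hz so the 60 Hz low-pass is below Nyquist.
#' @return the filtered [EEGRecording-class].
#' @export
applyFilters <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (fs <= 120)
    stop("configuration error: fs must exceed 120 Hz for the 60 Hz low-pass")
  nyq <- fs / 2
  hp <- signal::butter(4, 0.5 / nyq, type = "high")
  notch <- signal::butter(4, c(48, 52) / nyq, type = "stop")
  lp <- signal::butter(4, 60 / nyq, type = "low")
  x <- signalMatrix(rec)
  for (i in seq_len(nrow(x))) {
    v <- x[i, ] - mean(x[i, ])  # conditioning: avoid a DC step transient
    v <- zeroPhase(hp, v, fs = fs)
    v <- zeroPhase(notch, v, fs = fs)
    v <- zeroPhase(lp, v, fs = fs)
    x[i, ] <- v - mean(v)
  }
  EEGRecording(x, fs, channelLabels(rec))
}

#' Re-reference to a bipolar montage
#'
#' Each output channel is anode minus cathode, named `"anode-cathode"`,
#' in the order of the scheme.
#'
#' @param rec an [EEGRecording-class] holding all scheme labels.
#' @param scheme a [bipolarScheme()] data.frame.
#' @return an [EEGRecording-class] of derived channels.
#' @export
toBipolar <- function(rec, scheme = bipolarScheme()) {
  stopifnot(is(rec, "EEGRecording"))
  labels <- channelLabels(rec)
  missing <- setdiff(unique(c(scheme$anode, scheme$cathode)), labels)
  if (length(missing))
    stop("montage error: channel(s) not in recording: ",
         paste(missing, collapse = ", "))
  x <- signalMatrix(rec)
  out <- x[match(scheme$anode, labels), , drop = FALSE] -
    x[match(scheme$cathode, labels), , drop = FALSE]
  EEGRecording(out, samplingRate(rec), scheme$name)
}

#' Extract condition-labelled epochs around tap onsets
#'
#' Epochs cover `span[1]` s before to `span[2]` s after each onset
#' (`span[1]*fs + span[2]*fs` samples, onset at time 0) and are demeaned
#' per trial and channel. Events whose span does not fit inside the
#' recording are dropped with a warning.
#'
#' @param rec an [EEGRecording-class] (typically filtered and re-referenced).
#' @param events an [EventList-class] on the same sampling rate.
#' @param span seconds before / after onset (default `c(3, 3)`).
#' @return a [TrialSet-class].
#' @export
epochTrials <- function(rec, events, span = c(3, 3)) {
  stopifnot(is(rec, "EEGRecording"), is(events, "EventList"))
  fs <- samplingRate(rec)
  if (abs(fs - samplingRate(events)) > 1e-9)
    stop("recording and events disagree on sampling rate")
  nPre <- round(span[1] * fs); nPost <- round(span[2] * fs)
  L <- nPre + nPost
  n <- ncol(signalMatrix(rec))
  onsets <- eventOnsets(events)
  ok <- (onsets - nPre >= 1) & (onsets + nPost - 1 <= n)
  if (any(!ok))
    warning(sum(!ok), " event(s) dropped: epoch span outside the recording")
  if (!any(ok)) stop("empty-set error: no usable events")
  onsets <- onsets[ok]
  labels <- eventLabels(events)[ok]
  x <- signalMatrix(rec)
  nch <- nrow(x)
  ep <- array(0, dim = c(length(onsets), nch, L))
  for (k in seq_along(onsets)) {
    idx <- (onsets[k] - nPre):(onsets[k] + nPost - 1)
    seg <- x[, idx, drop = FALSE]
    ep[k, , ] <- seg - rowMeans(seg)
  }
  new("TrialSet", epochs = ep,
      timeAxis = (seq_len(L) - 1 - nPre) / fs,
      condition = labels, fs = fs, channelLabels = channelLabels(rec))
}

#' Sliding-window specification
#'
#' One-second windows shifted by 100 ms: the feature at end-time t is
#' computed on the interval `[t-1, t]`. For a `[-3, +3]` s epoch this
#' yields the 51-point grid `-2.0, -1.9, ..., +3.0`.
#'
#' @param length window length (s).
#' @param step window shift (s).
#' @param span epoch span (s before, s after onset).
#' @return a list with `length`, `step` and the `endTimes` grid.
#' @export
windowSpec <- function(length = 1, step = 0.1, span = c(3, 3)) {
  endTimes <- seq(-span[1] + length, span[2], by = step)
  list(length = length, step = step, span = span,
       endTimes = round(endTimes, 10))
}

#' Decompose a single-channel epoch into sliding windows
#'
#' @param x numeric vector, one channel of one epoch spanning
#'   `spec$span`.
#' @param spec a [windowSpec()].
#' @param fs sampling rate (Hz).
#' @param demean demean each window (default TRUE).
#' @return an `N x nWindows` matrix with `attr(, "endTimes")`; N =
#'   `round(spec$length * fs)`.
#' @export
slidingWindows <- function(x, spec, fs, demean = TRUE) {
  N <- round(spec$length * fs)
  nPre <- round(spec$span[1] * fs)
  ends <- round((spec$endTimes + spec$span[1]) * fs)
  if (any(ends > length(x)) || any(ends - N < 0))
    stop("windowing error: spec incompatible with epoch length")
  out <- vapply(ends, function(e) x[(e - N + 1):e], numeric(N))
  if (demean) out <- sweep(out, 2, colMeans(out))
  attr(out, "endTimes") <- spec$endTimes
  out
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth between `lo` and `hi` Hz, applied
#' forward-backward.
#'
#' @param x numeric vector or channels-x-time matrix.
#' @param lo,hi band edges (Hz); `hi` must be below Nyquist.
#' @param fs sampling rate (Hz).
#' @return the filtered object, same shape as `x`.
#' @export
bandpassFilter <- function(x, lo, hi, fs) {
  if (!(lo > 0 && lo < hi)) stop("configuration error: need 0 < lo < hi")
  if (hi >= fs / 2)
    stop("configuration error: hi must be below the Nyquist frequency")
  bp <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    for (i in seq_len(nrow(x))) x[i, ] <- zeroPhase(bp, x[i, ])
    x
  } else zeroPhase(bp, x)
}

# band-pass every trial x channel epoch of a TrialSet
bandpassTrials <- function(trials, lo, hi) {
  ep <- trialEpochs(trials)
  d <- dim(ep)
  fs <- samplingRate(trials)
  bp <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      ep[tr, ch, ] <- zeroPhase(bp, ep[tr, ch, ])
  new("TrialSet", epochs = ep, timeAxis = timeAxis(trials),
      condition = trialConditions(trials), fs = fs,
      channelLabels = channelLabels(trials))
}
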