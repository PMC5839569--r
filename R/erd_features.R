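#' Envelope of the squared signal
#'
#' Squares the input and interpolates linearly through the strict local
#' maxima (and, for `mode = "mean_of_both"`, minima) of the squared
#' signal, endpoints included. The result is the smoothed instantaneous
#' band power used by the ERD band-power method. With fewer than two
#' interior extrema the squared signal is returned unchanged with a note.
#'
#' @param x numeric vector, band-passed and zero-mean.
#' @param mode `"upper"` or `"mean_of_both"`.
#' @return nonnegative (for `"upper"`) numeric vector, same length as `x`.
#' @export
powerEnvelope <- function(x, mode = c("upper", "mean_of_both")) {
  mode <- match.arg(mode)
  p <- x^2
  n <- length(p)
  interpThrough <- function(idx) {
    idx <- unique(c(1L, idx, n))
    approx(idx, p[idx], xout = seq_len(n))$y
  }
  maxIdx <- localMaximaIdx(p, 2L, n - 1L)
  if (length(maxIdx) < 2) {
    message("powerEnvelope: fewer than 2 extrema; returning squared signal")
    return(p)
  }
  upper <- interpThrough(maxIdx)
  if (mode == "upper") return(upper)
  minIdx <- localMaximaIdx(-p, 2L, n - 1L)
  lower <- if (length(minIdx) >= 2) interpThrough(minIdx) else p
  (upper + lower) / 2
}

#' ERD percentage of a window relative to baseline
#'
#' `((A - R) / R) * 100`: negative values mean desynchronisation (power
#' loss relative to baseline), positive values synchronisation.
#'
#' @param A window mean power.
#' @param R baseline mean power, strictly positive.
#' @return ERD in percent.
#' @export
erdPercent <- function(A, R) {
  if (any(R <= 0)) stop("baseline error: baseline power must be positive")
  (A - R) / R * 100
}

erdBaselineIdx <- function(timeAxis, baselineInterval) {
  which(timeAxis >= baselineInterval[1] & timeAxis <= baselineInterval[2])
}

#' Single-trial ERD time courses
#'
#' Per trial and channel: band-pass, square, upper envelope, baseline mean
#' over `baselineInterval`, window means on the sliding grid, ERD percent.
#'
#' @param trials a [TrialSet-class].
#' @param lo,hi band edges (Hz).
#' @param spec a [windowSpec()].
#' @param baselineInterval `[start, end]` s relative to onset
#'   (default `c(-2, -1.5)`).
#' @param bandName label written to the output table.
#' @return a long data.frame: `condition`, `trial`, `channel`, `band`,
#'   `window_end_time_s`, `erd_percent`, `valid`.
#' @export
singleTrialErd <- function(trials, lo = 8, hi = 13, spec = windowSpec(),
                           baselineInterval = c(-2, -1.5),
                           bandName = "mu") {
  stopifnot(is(trials, "TrialSet"))
  checkBaseline(baselineInterval, trials)
  fs <- samplingRate(trials)
  trials <- bandpassTrials(trials, lo, hi)
  ep <- trialEpochs(trials)
  d <- dim(ep)
  bIdx <- erdBaselineIdx(timeAxis(trials), baselineInterval)
  res <- vector("list", d[1] * d[2])
  k <- 0
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      env <- suppressMessages(powerEnvelope(ep[tr, ch, ], "upper"))
      R <- mean(env[bIdx])
      wins <- slidingWindows(env, spec, fs, demean = FALSE)
      A <- colMeans(wins)
      ok <- R > 0
      k <- k + 1
      res[[k]] <- data.frame(
        condition = trialConditions(trials)[tr], trial = tr,
        channel = channelLabels(trials)[ch], band = bandName,
        window_end_time_s = spec$endTimes,
        erd_percent = if (ok) erdPercent(A, R) else NA_real_,
        valid = ok)
    }
  }
  do.call(rbind, res)
}

#' Grand-average ERD by the band-power method
#'
#' Per channel and condition: band-pass each trial, remove the evoked
#' response (subtract the pointwise cross-trial mean of the band-passed
#' signal), square, average across trials, smooth by the mean of the upper
#' and lower envelopes, then express each sliding window relative to the
#' baseline interval as ERD percent.
#'
#' @inheritParams singleTrialErd
#' @return a data.frame: `condition`, `channel`, `band`,
#'   `window_end_time_s`, `erd_percent`.
#' @export
grandAverageErd <- function(trials, lo = 8, hi = 13, spec = windowSpec(),
                            baselineInterval = c(-2, -1.5),
                            bandName = "mu") {
  stopifnot(is(trials, "TrialSet"))
  checkBaseline(baselineInterval, trials)
  fs <- samplingRate(trials)
  trials <- bandpassTrials(trials, lo, hi)
  ep <- trialEpochs(trials)
  conds <- trialConditions(trials)
  bIdx <- erdBaselineIdx(timeAxis(trials), baselineInterval)
  res <- list()
  for (cond in unique(conds)) {
    sel <- which(conds == cond)
    if (length(sel) < 2)
      stop("empty-set error: need at least 2 trials per condition")
    for (ch in seq_along(channelLabels(trials))) {
      seg <- ep[sel, ch, , drop = FALSE][, 1, ]   # trials x samples
      resid <- sweep(seg, 2, colMeans(seg))       # evoked removal
      meanPow <- colMeans(resid^2)
      if (all(meanPow < .Machine$double.eps))
        stop("degenerate-variance condition: identical trials leave no ",
             "residual band power")
      # powerEnvelope squares its input, so feed the root of the mean
      # power: the envelope smoothing then acts on the power curve itself
      smooth <- suppressMessages(powerEnvelope(sqrt(meanPow),
                                               "mean_of_both"))
      R <- mean(smooth[bIdx])
      wins <- slidingWindows(smooth, spec, fs, demean = FALSE)
      res[[length(res) + 1]] <- data.frame(
        condition = cond, channel = channelLabels(trials)[ch],
        band = bandName, window_end_time_s = spec$endTimes,
        erd_percent = erdPercent(colMeans(wins), R))
    }
  }
  do.call(rbind, res)
}

checkBaseline <- function(baselineInterval, trials) {
  ta <- timeAxis(trials)
  if (baselineInterval[1] >= baselineInterval[2] ||
      baselineInterval[2] > 0 ||
      baselineInterval[1] < min(ta))
    stop("baseline interval must precede onset and lie inside the epoch")
}

#' Event-related spectral perturbation map
#'
#' Short-time Fourier spectrograms (0.5 s Hann segments, 90% overlap,
#' power scaling) averaged per condition and channel; the map is the
#' movement-minus-rest difference in dB, averaged over channels.
#'
#' @param trials a [TrialSet-class].
#' @param moveCondition,restCondition condition labels to contrast.
#' @param fMax highest frequency retained (Hz).
#' @return a list with `times` (s, epoch time), `freqs` (Hz) and `values`
#'   (freqs x times matrix, dB).
#' @export
erspMap <- function(trials, moveCondition = "right",
                    restCondition = "rest", fMax = 60) {
  stopifnot(is(trials, "TrialSet"))
  fs <- samplingRate(trials)
  conds <- trialConditions(trials)
  for (cond in c(moveCondition, restCondition))
    if (sum(conds == cond) < 2)
      stop("empty-set error: need at least 2 trials of condition ", cond)
  n <- round(0.5 * fs)
  hop <- max(1, round(0.1 * n))
  win <- signal::hanning(n)
  ep <- trialEpochs(trials)
  starts <- seq(1, dim(ep)[3] - n + 1, by = hop)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= 0.5 & freqs <= fMax
  avgPower <- function(sel) {
    acc <- matrix(0, sum(keep), length(starts))
    for (tr in sel) for (ch in seq_len(dim(ep)[2])) {
      x <- ep[tr, ch, ]
      P <- vapply(starts, function(s0) {
        Mod(fft(x[s0:(s0 + n - 1)] * win))[keep]^2
      }, numeric(sum(keep)))
      acc <- acc + P
    }
    acc / (length(sel) * dim(ep)[2])
  }
  Pm <- avgPower(which(conds == moveCondition))
  Pr <- avgPower(which(conds == restCondition))
  eps <- .Machine$double.xmin
  list(times = timeAxis(trials)[starts + round(n / 2)],
       freqs = freqs[keep],
       values = 10 * log10((Pm + eps) / (Pr + eps)))
}
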