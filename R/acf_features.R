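#' Normalised autocorrelation of a signal window
#'
#' For a zero-mean window s(0..N-1), the autocorrelation at lag `k` is the
#' sum of products of mean-deviations k samples apart, normalised by the
#' zero-lag sum of squared deviations, so that R(0) = 1 and |R(k)| <= 1.
#' Computed via FFT; a brute-force double loop gives identical values to
#' numerical precision.
#'
#' @param w numeric window (at least 8 samples, non-constant).
#' @param fs sampling rate (Hz).
#' @param maxLag largest lag in samples (default `length(w) - 1`).
#' @return a list with `lags` (samples, 0..maxLag), `values` and `fs`.
#' @export
normalizedAutocorrelation <- function(w, fs, maxLag = length(w) - 1) {
  N <- length(w)
  if (N < 8) stop("window too short: need N >= 8")
  d <- w - mean(w)
  ss <- sum(d^2)
  if (ss <= 0) stop("degenerate-window error: zero variance")
  M <- nextn(2L * N, 2)
  f <- fft(c(d, numeric(M - N)))
  s <- Re(fft(Mod(f)^2, inverse = TRUE)) / M
  list(lags = 0:maxLag, values = s[1:(maxLag + 1)] / s[1], fs = fs)
}

# acf of every column of a window matrix at once (columns already or not
# demeaned); returns (maxLag+1) x K matrix, NA columns for zero variance.
acfMatrix <- function(wins, maxLag) {
  N <- nrow(wins)
  wins <- sweep(wins, 2, colMeans(wins))
  M <- nextn(2L * N, 2)
  F <- stats::mvfft(rbind(wins, matrix(0, M - N, ncol(wins))))
  S <- Re(stats::mvfft(Mod(F)^2, inverse = TRUE)) / M
  S <- S[1:(maxLag + 1), , drop = FALSE]
  z <- S[1, ] <= .Machine$double.eps * N
  out <- sweep(S, 2, S[1, ], "/")
  out[, z] <- NA_real_
  out
}

#' Local maxima of an autocorrelation sequence
#'
#' Returns the anchor point (lag 0, value 1) followed by all strict local
#' maxima of R over lags `1..maxLag` (plateaus contribute their first
#' sample); only points with positive value are retained, since the
#' exponential decay model is positive.
#'
#' @param acf result of [normalizedAutocorrelation()].
#' @param maxLag search cap in samples; defaults to half the window
#'   length, i.e. half of the total positive lags.
#' @return a data.frame with columns `lag_s` (seconds) and `value`.
#' @export
acfLocalMaxima <- function(acf, maxLag = NULL) {
  v <- acf$values
  N <- length(v)
  if (is.null(maxLag)) maxLag <- floor((N - 1) / 2)
  maxLag <- min(maxLag, N - 2)  # need a right neighbour
  idx <- localMaximaIdx(v, 2L, maxLag + 1L)
  keep <- idx[v[idx] > 0]
  data.frame(lag_s = c(0, (keep - 1) / acf$fs),
             value = c(1, v[keep]))
}

# strict local maxima of v between positions lo..hi (1-based), plateaus
# broken by their first sample; neighbours may lie outside [lo, hi].
localMaximaIdx <- function(v, lo, hi) {
  out <- integer(0)
  i <- lo
  while (i <= hi) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j < length(v) && v[j + 1] == v[i]) j <- j + 1
      if (j < length(v) && v[j + 1] < v[i]) out <- c(out, i)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

#' Fit the exponential relaxation model to autocorrelation maxima
#'
#' Fits `R(t) ~ C * exp(-t / tau)` with C fixed at 1 (the autocorrelation
#' is normalised) by least squares in tau over `[1e-4, 10]` s. The
#' optimizer is a bounded 1-D search seeded by the slope of a least-squares
#' line through (t, log y). R-squared uses the total sum of squares about
#' the mean of the fitted points (anchor included).
#'
#' @param points data.frame from [acfLocalMaxima()] (`lag_s`, `value`).
#' @param bounds search interval for tau (s).
#' @return a list with `tau` (s), `C` (always 1), `rSquared`, `nPoints`,
#'   `valid`. Fewer than 3 points gives `valid = FALSE`.
#' @export
fitRelaxation <- function(points, bounds = c(1e-4, 10)) {
  invalid <- list(tau = NA_real_, C = 1, rSquared = NA_real_,
                  nPoints = nrow(points), valid = FALSE)
  if (is.null(points) || nrow(points) < 3) return(invalid)
  t <- points$lag_s; y <- points$value
  sse <- function(tau) sum((exp(-t / tau) - y)^2)
  # log-linear seed narrows the bracket when it is informative
  lower <- bounds[1]; upper <- bounds[2]
  pos <- y > 0 & t > 0
  if (sum(pos) >= 2) {
    slope <- sum((t[pos] - mean(t[pos])) * (log(y[pos]) -
                 mean(log(y[pos])))) / sum((t[pos] - mean(t[pos]))^2)
    if (is.finite(slope) && slope < 0) {
      seed <- max(lower, min(upper, -1 / slope))
      # keep full bounds: the seed only provides a candidate to compare
      candidate <- seed
    } else candidate <- NULL
  } else candidate <- NULL
  opt <- tryCatch(optimize(sse, c(lower, upper), tol = 1e-9),
                  error = function(e) NULL)
  if (is.null(opt)) return(invalid)
  tau <- opt$minimum
  if (!is.null(candidate) && sse(candidate) < opt$objective) {
    # polish from the seed in a local bracket
    loc <- tryCatch(optimize(sse, c(max(lower, candidate / 10),
                                    min(upper, candidate * 10)),
                             tol = 1e-9), error = function(e) NULL)
    if (!is.null(loc) && loc$objective < opt$objective) tau <- loc$minimum
  }
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse(tau) / sst else as.numeric(sse(tau) == 0)
  list(tau = tau, C = 1, rSquared = min(1, max(0, r2)),
       nPoints = length(t), valid = TRUE)
}

#' Relaxation time of a single window
#'
#' Convenience chain: normalised autocorrelation, local maxima over half
#' the positive lags, exponential fit.
#'
#' @param w numeric window.
#' @param fs sampling rate (Hz).
#' @return a [fitRelaxation()] result.
#' @export
fitWindowTau <- function(w, fs) {
  acf <- tryCatch(normalizedAutocorrelation(w, fs),
                  error = function(e) NULL)
  if (is.null(acf))
    return(list(tau = NA_real_, C = 1, rSquared = NA_real_, nPoints = 0L,
                valid = FALSE))
  fitRelaxation(acfLocalMaxima(acf))
}

#' Relaxation-time time course of every trial and channel
#'
#' Band-pass filters each epoch, slides the 1 s / 100 ms window grid over
#' it, and fits the relaxation time in every window. Windows whose fit
#' fails are flagged invalid; a trial with more than half of its windows
#' invalid is excluded as a whole (column `trial_valid`).
#'
#' @param trials a [TrialSet-class] (preprocessed, bipolar).
#' @param lo,hi band edges (Hz); use `NULL` for no additional filtering.
#' @param spec a [windowSpec()] matching the trial span.
#' @param bandName label written to the output table.
#' @return a long data.frame: `condition`, `trial`, `channel`, `band`,
#'   `window_end_time_s`, `tau_s`, `r_squared`, `valid`, `trial_valid`.
#' @export
tauTimecourse <- function(trials, lo = 0.5, hi = 30, spec = windowSpec(),
                          bandName = "wide") {
  stopifnot(is(trials, "TrialSet"))
  fs <- samplingRate(trials)
  if (!is.null(lo)) trials <- bandpassTrials(trials, lo, hi)
  ep <- trialEpochs(trials)
  d <- dim(ep)
  chs <- channelLabels(trials)
  conds <- trialConditions(trials)
  N <- round(spec$length * fs)
  maxLag <- floor(N / 2)
  nW <- length(spec$endTimes)
  res <- vector("list", d[1] * d[2])
  k <- 0
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      wins <- slidingWindows(ep[tr, ch, ], spec, fs)
      am <- acfMatrix(wins, maxLag)
      tau <- r2 <- rep(NA_real_, nW)
      ok <- rep(FALSE, nW)
      for (wi in seq_len(nW)) {
        if (is.na(am[1, wi])) next
        pts <- acfLocalMaxima(list(values = am[, wi], fs = fs))
        fit <- fitRelaxation(pts)
        if (fit$valid) {
          tau[wi] <- fit$tau; r2[wi] <- fit$rSquared; ok[wi] <- TRUE
        }
      }
      k <- k + 1
      res[[k]] <- data.frame(
        condition = conds[tr], trial = tr, channel = chs[ch],
        band = bandName, window_end_time_s = spec$endTimes,
        tau_s = tau, r_squared = r2, valid = ok,
        trial_valid = mean(ok) >= 0.5)
    }
  }
  out <- do.call(rbind, res)
  nBad <- length(unique(out$trial[!out$trial_valid]))
  if (nBad > 0)
    warning(nBad, " trial(s) flagged: more than half of their windows ",
            "failed the relaxation fit")
  out
}

#' Grand-average relaxation-time curves
#'
#' Pointwise mean and standard deviation of tau over trials, per channel
#' and condition, ignoring invalid windows; the contributing count is
#' reported per point.
#'
#' @param tauTable output of [tauTimecourse()] (possibly several sessions
#'   row-bound, with a `participant` column for cohorts).
#' @return a data.frame: `condition`, `channel`, `band`,
#'   `window_end_time_s`, `mean_tau_s`, `sd_tau_s`, `n`.
#' @export
grandAverageTau <- function(tauTable) {
  ok <- tauTable$valid & tauTable$trial_valid
  if (!any(ok)) stop("empty-set error: no valid windows to average")
  tab <- tauTable[ok, ]
  agg <- aggregate(tau_s ~ condition + channel + band + window_end_time_s,
                   data = tab,
                   FUN = function(v) c(mean(v), sd(v), length(v)))
  data.frame(agg[, 1:4],
             mean_tau_s = agg$tau_s[, 1],
             sd_tau_s = agg$tau_s[, 2],
             n = agg$tau_s[, 3])
}
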