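# save/restore the global RNG so seeded CV does not perturb callers
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Cross-validation scheme
#'
#' Ten repeats of ten stratified splits. The default `"shuffle"` type
#' draws independent 80/20 stratified splits (honouring the stated
#' training/testing fractions); `"kfold"` gives strict stratified 10-fold
#' partitions per repeat.
#'
#' @param nRepeats,nSplits repeats and splits per repeat.
#' @param testFraction held-out fraction per split (shuffle type).
#' @param seed integer base seed.
#' @param type `"shuffle"` or `"kfold"`.
#' @return a list used by [cvSensitivity()].
#' @export
cvScheme <- function(nRepeats = 10, nSplits = 10, testFraction = 0.2,
                     seed = 1L, type = c("shuffle", "kfold")) {
  list(nRepeats = nRepeats, nSplits = nSplits,
       testFraction = testFraction, seed = as.integer(seed),
       type = match.arg(type))
}

# univariate two-class LDA with pooled variance and equal priors;
# returns TRUE where x is classified as class 1 (tap)
ldaPredictTap <- function(xTrainTap, xTrainRest, xTest) {
  m1 <- mean(xTrainTap); m0 <- mean(xTrainRest)
  n1 <- length(xTrainTap); n0 <- length(xTrainRest)
  s2 <- (sum((xTrainTap - m1)^2) + sum((xTrainRest - m0)^2)) /
    (n1 + n0 - 2)
  # degenerate training (no separation or zero spread): chance-level
  # guessing, seeded by the caller's CV stream
  if (s2 <= 0 || m1 == m0)
    return(runif(length(xTest)) < 0.5)
  # equal priors: the discriminant reduces to the midpoint rule along the
  # direction of the class-mean difference
  d1 <- xTest * m1 / s2 - m1^2 / (2 * s2)
  d0 <- xTest * m0 / s2 - m0^2 / (2 * s2)
  d1 > d0
}

#' Cross-validated sensitivity of a univariate feature
#'
#' For every stratified split, a two-class linear discriminant (pooled
#' variance, equal priors) is fitted on the training portion and the
#' sensitivity (true-positive rate: tap-class test trials classified tap)
#' is pooled per repeat. Trials with a non-finite feature value are
#' dropped first.
#'
#' @param values numeric feature vector (tau in seconds or ERD percent).
#' @param isTap logical vector, TRUE for tap trials.
#' @param scheme a [cvScheme()].
#' @return a list: `sensitivity` (mean over repeats), `sd` (over repeats),
#'   `nTap`, `nRest` (trials used), `perRepeat`.
#' @export
cvSensitivity <- function(values, isTap, scheme = cvScheme()) {
  keep <- is.finite(values)
  values <- values[keep]; isTap <- isTap[keep]
  iTap <- which(isTap); iRest <- which(!isTap)
  if (length(iTap) < 5 || length(iRest) < 5)
    stop("need at least 5 valid trials per class")
  perRepeat <- withSeed(scheme$seed, {
    vapply(seq_len(scheme$nRepeats), function(r) {
      correct <- 0; total <- 0
      if (scheme$type == "kfold") {
        foldTap <- sample(rep_len(seq_len(scheme$nSplits), length(iTap)))
        foldRest <- sample(rep_len(seq_len(scheme$nSplits), length(iRest)))
      }
      for (s in seq_len(scheme$nSplits)) {
        if (scheme$type == "shuffle") {
          testTap <- sample(iTap, max(1, round(scheme$testFraction *
                                               length(iTap))))
          testRest <- sample(iRest, max(1, round(scheme$testFraction *
                                                 length(iRest))))
        } else {
          testTap <- iTap[foldTap == s]
          testRest <- iRest[foldRest == s]
        }
        trTap <- setdiff(iTap, testTap); trRest <- setdiff(iRest, testRest)
        if (!length(trTap) || !length(trRest)) next
        pred <- ldaPredictTap(values[trTap], values[trRest],
                              values[testTap])
        correct <- correct + sum(pred)
        total <- total + length(testTap)
      }
      if (total == 0) NA_real_ else correct / total
    }, numeric(1))
  })
  list(sensitivity = mean(perRepeat, na.rm = TRUE),
       sd = sd(perRepeat, na.rm = TRUE),
       nTap = length(iTap), nRest = length(iRest),
       perRepeat = perRepeat)
}

#' Binomial chance-level threshold for two-class sensitivity
#'
#' The smallest classification rate k/n whose probability under random
#' guessing (Binomial(n, 1/2)) has upper-tail mass at most `alpha`:
#' `P(X >= k) <= alpha`. Sensitivities above the threshold are better than
#' chance at the `1 - alpha` confidence level.
#'
#' @param nTrials number of trials entering the classification.
#' @param alpha significance level (default 0.05).
#' @return the threshold as a fraction in `[0, 1]`.
#' @examples
#' binomialThreshold(40)  # 26/40 = 0.65
#' @export
binomialThreshold <- function(nTrials, alpha = 0.05) {
  if (nTrials < 10)
    stop("configuration error: threshold unreliable for fewer than 10 trials")
  if (alpha >= 1) return(0)
  k <- qbinom(alpha, nTrials, 0.5, lower.tail = FALSE) + 1
  # guard against quantile edge cases: enforce the defining inequality
  while (k > 0 && pbinom(k - 2, nTrials, 0.5, lower.tail = FALSE) <= alpha)
    k <- k - 1
  while (pbinom(k - 1, nTrials, 0.5, lower.tail = FALSE) > alpha)
    k <- k + 1
  k / nTrials
}

#' Sensitivity curve over the sliding-window grid
#'
#' Applies [cvSensitivity()] independently per channel and window. The CV
#' seed of each window is the scheme's base seed plus the window index, so
#' curves are reproducible without coupling windows.
#'
#' @param features long data.frame with columns `channel`,
#'   `window_end_time_s`, `trial`, `value`, `is_tap` (see
#'   [classificationFeatures()]).
#' @param scheme a [cvScheme()].
#' @return a data.frame: `channel`, `end_time_s`, `sensitivity`, `sd`,
#'   `n_tap`, `n_rest`.
#' @export
sensitivityCurve <- function(features, scheme = cvScheme()) {
  grid <- sort(unique(features$window_end_time_s))
  res <- list()
  for (ch in unique(features$channel)) {
    for (wi in seq_along(grid)) {
      sub <- features[features$channel == ch &
                      features$window_end_time_s == grid[wi], ]
      wscheme <- scheme
      wscheme$seed <- scheme$seed + wi
      cv <- tryCatch(cvSensitivity(sub$value, sub$is_tap, wscheme),
                     error = function(e) NULL)
      res[[length(res) + 1]] <- data.frame(
        channel = ch, end_time_s = grid[wi],
        sensitivity = if (is.null(cv)) NA_real_ else cv$sensitivity,
        sd = if (is.null(cv)) NA_real_ else cv$sd,
        n_tap = if (is.null(cv)) 0L else cv$nTap,
        n_rest = if (is.null(cv)) 0L else cv$nRest)
    }
  }
  do.call(rbind, res)
}

#' Assemble classification features from a feature table
#'
#' Reshapes the long tau or ERD table into the per-window feature layout
#' consumed by [sensitivityCurve()], keeping the tap condition and rest
#' trials only and dropping invalid windows.
#'
#' @param table output of [tauTimecourse()] or [singleTrialErd()].
#' @param tapCondition `"right"` or `"left"`.
#' @param valueColumn `"tau_s"` or `"erd_percent"`.
#' @return a data.frame with `channel`, `window_end_time_s`, `trial`,
#'   `value`, `is_tap`.
#' @export
classificationFeatures <- function(table, tapCondition = "right",
                                   valueColumn = c("tau_s",
                                                   "erd_percent")) {
  valueColumn <- match.arg(valueColumn)
  keep <- table$condition %in% c(tapCondition, "rest")
  if ("trial_valid" %in% names(table)) keep <- keep & table$trial_valid
  tab <- table[keep & table$valid, ]
  data.frame(channel = tab$channel,
             window_end_time_s = tab$window_end_time_s,
             trial = tab$trial, value = tab[[valueColumn]],
             is_tap = tab$condition == tapCondition)
}

#' Detection timing from a sensitivity curve
#'
#' The first-crossing time is the earliest window end-time at which the
#' sensitivity reaches the chance threshold (negative values mean
#' detection before movement onset); the peak sensitivity and its time are
#' always reported.
#'
#' @param curve one channel's rows of a [sensitivityCurve()] result.
#' @param threshold sensitivity fraction from [binomialThreshold()].
#' @return a list: `threshold`, `first_crossing_time` (or `NA`),
#'   `peak_sensitivity`, `peak_time`, `channel`.
#' @export
detectTiming <- function(curve, threshold) {
  if (!nrow(curve)) stop("empty sensitivity curve")
  curve <- curve[order(curve$end_time_s), ]
  ok <- which(is.finite(curve$sensitivity))
  cross <- ok[curve$sensitivity[ok] >= threshold]
  peak <- ok[which.max(curve$sensitivity[ok])]
  list(threshold = threshold,
       first_crossing_time = if (length(cross))
         curve$end_time_s[cross[1]] else NA_real_,
       peak_sensitivity = curve$sensitivity[peak],
       peak_time = curve$end_time_s[peak],
       channel = curve$channel[1])
}

#' Most responsive channel
#'
#' Selects the channel with the highest peak sensitivity; ties are broken
#' by the earlier peak time, then by channel order.
#'
#' @param curves a [sensitivityCurve()] result over several channels.
#' @param threshold chance threshold (fraction).
#' @param channelOrder tie-break order (default: order of appearance).
#' @return a list: `best_channel`, `detection` (its [detectTiming()]
#'   result) and `perChannel` (data.frame of all channels).
#' @export
selectBestChannel <- function(curves, threshold,
                              channelOrder = unique(curves$channel)) {
  if (!nrow(curves)) stop("empty-set error: no channel curves")
  dets <- lapply(channelOrder, function(ch) {
    sub <- curves[curves$channel == ch, ]
    if (!nrow(sub) || !any(is.finite(sub$sensitivity))) return(NULL)
    detectTiming(sub, threshold)
  })
  keep <- !vapply(dets, is.null, logical(1))
  if (!any(keep)) stop("empty-set error: no usable channel curves")
  dets <- dets[keep]; chs <- channelOrder[keep]
  tab <- data.frame(
    channel = chs,
    peak_sensitivity = vapply(dets, `[[`, 0, "peak_sensitivity"),
    peak_time = vapply(dets, `[[`, 0, "peak_time"),
    first_crossing_time = vapply(dets, `[[`, 0, "first_crossing_time"))
  best <- order(-tab$peak_sensitivity, tab$peak_time,
                seq_len(nrow(tab)))[1]
  list(best_channel = tab$channel[best], detection = dets[[best]],
       perChannel = tab)
}
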