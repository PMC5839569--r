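#' Per-participant tap-vs-rest t-test on relaxation time
#'
#' Per channel: each trial is summarised by its mean valid tau over the
#' windows ending inside `onsetWindow` (default `[-0.5, +1]` s, where the
#' build-up of temporal dependence is expected), and tap and rest trials
#' are compared with Welch's two-sample t-test.
#'
#' @param tauTable output of [tauTimecourse()].
#' @param tapCondition `"right"` or `"left"`.
#' @param onsetWindow `[start, end]` s of window end-times entering the
#'   per-trial summary.
#' @return a data.frame per channel: `channel`, `statistic`, `df`,
#'   `p_value`, `mean_tap`, `mean_rest`, `n_tap`, `n_rest`, `skipped`.
#' @export
tauTapVsRestTest <- function(tauTable, tapCondition = "right",
                             onsetWindow = c(-0.5, 1)) {
  tab <- tauTable[tauTable$valid & tauTable$trial_valid &
                  tauTable$condition %in% c(tapCondition, "rest") &
                  tauTable$window_end_time_s >= onsetWindow[1] &
                  tauTable$window_end_time_s <= onsetWindow[2], ]
  res <- list()
  for (ch in unique(tab$channel)) {
    sub <- tab[tab$channel == ch, ]
    per <- aggregate(tau_s ~ trial + condition, sub, mean)
    x <- per$tau_s[per$condition == tapCondition]
    y <- per$tau_s[per$condition == "rest"]
    if (length(x) < 5 || length(y) < 5)
      stop("need at least 5 per-trial values per group")
    if (var(x) == 0 && var(y) == 0) {
      res[[length(res) + 1]] <- data.frame(
        channel = ch, statistic = NA_real_, df = NA_real_,
        p_value = NA_real_, mean_tap = mean(x), mean_rest = mean(y),
        n_tap = length(x), n_rest = length(y), skipped = TRUE)
      next
    }
    tt <- t.test(x, y)  # Welch
    res[[length(res) + 1]] <- data.frame(
      channel = ch, statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value,
      mean_tap = mean(x), mean_rest = mean(y),
      n_tap = length(x), n_rest = length(y), skipped = FALSE)
  }
  do.call(rbind, res)
}

#' Holm-Bonferroni step-down decisions
#'
#' Sorts the p-values ascending and rejects the i-th smallest while
#' `p(i) <= alpha / (m - i + 1)`, stopping at the first failure; decisions
#' are returned in the original order. Anything Bonferroni rejects, this
#' procedure also rejects.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return a data.frame: `p_value`, `reject`, `adjusted_p` (monotone
#'   step-down adjusted p-values), `alpha`.
#' @export
holmBonferroni <- function(p, alpha = 0.05) {
  if (!length(p)) return(data.frame(p_value = numeric(0),
                                    reject = logical(0),
                                    adjusted_p = numeric(0),
                                    alpha = numeric(0)))
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE else break
  }
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  adjusted <- numeric(m); adjusted[o] <- adj
  data.frame(p_value = p, reject = reject, adjusted_p = adjusted,
             alpha = alpha)
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired (or one-sample) two-sided signed-rank test. All absolute
#' differences, zeros included, are ranked together (midranks for ties);
#' zero differences are then discarded and the statistic is the sum of
#' ranks of the positive differences (the Pratt convention). With at most
#' 25 nonzero pairs the exact conditional null distribution is computed by
#' dynamic programming over the (doubled, hence integer) ranks; larger
#' samples use the normal approximation with continuity and tie
#' correction.
#'
#' @param x numeric vector (or differences if `y` is NULL).
#' @param y optional paired second sample.
#' @return a list: `statistic` (W+), `p_value`, `n_nonzero`, `method`.
#' @export
wilcoxonSignedRank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  r <- rank(abs(d))            # zeros included in the ranking
  nz <- d != 0
  rNz <- r[nz]
  W <- sum(rNz[d[nz] > 0])
  n <- sum(nz)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                method = "degenerate"))
  if (n <= 25) {
    r2 <- round(2 * rNz)       # doubled midranks are integers
    tot <- sum(r2)
    # distribution of the doubled statistic over random sign assignments
    f <- numeric(tot + 1); f[1] <- 1
    for (ri in r2) {
      g <- numeric(tot + 1)
      g[(ri + 1):(tot + 1)] <- f[1:(tot + 1 - ri)]
      f <- (f + g) / 2
    }
    W2 <- round(2 * W)
    pLo <- sum(f[1:(W2 + 1)])
    pHi <- sum(f[(W2 + 1):(tot + 1)])
    p <- min(1, 2 * min(pLo, pHi))
    method <- "exact"
  } else {
    E <- sum(rNz) / 2
    V <- sum(rNz^2) / 4
    z <- W - E
    z <- (z - sign(z) * 0.5) / sqrt(V)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n_nonzero = as.integer(n),
       method = method)
}

#' Band-pair comparison of peak sensitivities
#'
#' For one feature family, performs the paired Wilcoxon signed-rank test
#' on participants' peak sensitivities for each of the six band pairs and
#' applies the Holm-Bonferroni correction over the six p-values.
#'
#' @param summaries data.frame with columns `participant`, `band`,
#'   `feature`, `peak_sensitivity` (one row per participant x band x
#'   feature).
#' @param feature `"acf"` or `"erd"`.
#' @param alpha family-wise error level.
#' @return a data.frame, one row per band pair: `comparison`,
#'   `statistic`, `p_value`, `adjusted_p`, `reject`.
#' @export
bandComparison <- function(summaries, feature = "acf", alpha = 0.05) {
  tab <- summaries[summaries$feature == feature, ]
  bands <- standardBands()$name
  if (length(unique(tab$participant)) < 6)
    warning("fewer than 6 participants: band comparison is underpowered")
  pairs <- utils::combn(bands, 2)
  stat <- p <- numeric(ncol(pairs)); lab <- character(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- tab[tab$band == pairs[1, i], ]
    b <- tab[tab$band == pairs[2, i], ]
    m <- merge(a, b, by = "participant", suffixes = c(".a", ".b"))
    w <- wilcoxonSignedRank(m$peak_sensitivity.a, m$peak_sensitivity.b)
    stat[i] <- w$statistic; p[i] <- w$p_value
    lab[i] <- paste(pairs[1, i], "vs", pairs[2, i])
  }
  hb <- holmBonferroni(p, alpha)
  data.frame(comparison = lab, statistic = stat, p_value = p,
             adjusted_p = hb$adjusted_p, reject = hb$reject)
}

#' Pooled ACF-vs-ERD comparison
#'
#' Paired Wilcoxon signed-rank test over all participant x band pairs of
#' peak sensitivities, pooling the four bands, contrasting the
#' relaxation-time and ERD feature families.
#'
#' @param summaries as in [bandComparison()], containing both features.
#' @return a one-row data.frame: `comparison`, `statistic`, `p_value`,
#'   `n_pairs`, `underpowered`.
#' @export
featureComparison <- function(summaries) {
  a <- summaries[summaries$feature == "acf", ]
  b <- summaries[summaries$feature == "erd", ]
  m <- merge(a, b, by = c("participant", "band"),
             suffixes = c(".acf", ".erd"))
  under <- nrow(m) < 6
  if (under)
    warning("fewer than 6 pairs: comparison is underpowered")
  w <- wilcoxonSignedRank(m$peak_sensitivity.acf, m$peak_sensitivity.erd)
  data.frame(comparison = "acf vs erd (pooled bands)",
             statistic = w$statistic, p_value = w$p_value,
             n_pairs = nrow(m), underpowered = under)
}
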