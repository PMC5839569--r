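# shared fixtures, memoised so expensive simulations run once per suite

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# long stationary AR(2) realization cut into non-overlapping 1 s windows
arWindows <- function(rho, nWindows, fs = 1024, fOsc = 10, seed = 1) {
  set.seed(seed)
  a <- relaxEEG:::arCoefficients(rho, fOsc, fs)
  burn <- 4 * fs
  x <- as.numeric(stats::filter(rnorm(nWindows * fs + burn), a,
                                method = "recursive"))
  x <- x[-(1:burn)]
  matrix(x, nrow = fs)
}

# median fitted relaxation time over stationary AR(2) windows
medianFittedTau <- function(rho, nWindows, fs = 1024, seed = 1) {
  wins <- arWindows(rho, nWindows, fs = fs, seed = seed)
  taus <- apply(wins, 2, function(w) fitWindowTau(w, fs)$tau)
  median(taus, na.rm = TRUE)
}

# small preprocessed session for feature-level tests
smallSession <- function(seed = 1, nPer = 12, fs = 1024,
                         conditions = c("right", "rest"), ...) {
  cfg <- synthConfig(fs = fs, nTrialsPerCondition = nPer,
                     conditions = conditions,
                     channelLabels = c("C3", "Cz", "P3", "Pz"),
                     seed = seed, ...)
  ses <- generateSession(cfg)
  scheme <- bipolarScheme(cbind(c("C3", "Cz"), c("P3", "Pz")))
  trials <- epochTrials(toBipolar(applyFilters(ses$recording), scheme),
                        ses$events)
  list(trials = trials, session = ses, config = cfg)
}

# full study-scale session -> tau feature table and curves (per seed)
defaultTauRun <- function(seed) {
  cached(paste0("run", seed), {
    cfg <- synthConfig(nTrialsPerCondition = 40,
                       conditions = c("right", "rest"), seed = seed)
    ses <- generateSession(cfg)
    trials <- epochTrials(toBipolar(applyFilters(ses$recording)),
                          ses$events)
    tau <- tauTimecourse(trials, 0.5, 30)
    fm <- classificationFeatures(tau, "right", "tau_s")
    curves <- sensitivityCurve(fm, cvScheme(seed = seed))
    list(tau = tau, features = fm, curves = curves,
         threshold = binomialThreshold(40))
  })
}

# brute-force normalised autocorrelation straight from its definition
bruteAcf <- function(w, maxLag = length(w) - 1) {
  N <- length(w)
  d <- w - mean(w)
  denom <- sum(d^2)
  vapply(0:maxLag, function(lag) {
    s <- 0
    for (t in 1:(N - lag)) s <- s + d[t] * d[t + lag]
    s / denom
  }, numeric(1))
}

# enumeration oracle for the signed-rank test with Pratt zero handling
enumSignedRank <- function(d) {
  r <- rank(abs(d))
  nz <- which(d != 0)
  rNz <- r[nz]
  W <- sum(rNz[d[nz] > 0])
  n <- length(nz)
  Ws <- vapply(0:(2^n - 1), function(mask) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    sum(rNz[sel])
  }, numeric(1))
  pLo <- mean(Ws <= W + 1e-12)
  pHi <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(pLo, pHi))
}
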