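# relaxEEG

Detects voluntary movement intention in multichannel EEG from the
**relaxation time of the signal's autocorrelation**, and compares it
against the classical event-related desynchronisation (ERD) band-power
marker.

Brain-computer interfaces built on self-paced movement need a marker
that anticipates the movement itself. The usual one, ERD, is a drop in
mu-band (8-13 Hz) power and is frequency- and subject-specific. This
package implements a complementary, frequency-independent time-domain
marker: during movement preparation the EEG's temporal dependencies
lengthen, so the autocorrelation of a short window decays more slowly
than at rest. Each 1 s sliding window (stepped by 100 ms over 6 s
epochs time-locked to a tap onset) is summarised by fitting

    R(Δ) ~ C · exp(-t/τ),  C = 1 (normalised autocorrelation)

to the positive local maxima of the window's normalised autocorrelation
over the first half of the positive lags. The decay constant τ
(seconds) is the feature: large τ = slow decay = long-lived temporal
dependence. Per channel and per window, a two-class linear discriminant
(tap vs rest, univariate, pooled variance, equal priors) under a 10x10
cross-validation scheme yields a sensitivity curve over the trial;
crossing the exact Binomial(n, 1/2) chance threshold marks the
detection time (negative = prediction before movement onset). Group
comparisons use Welch t-tests on per-trial onset-window τ, and paired
Wilcoxon signed-rank tests with Holm-Bonferroni correction across the
four frequency bands (0.5-8, 8-13, 13-30, 0.5-30 Hz).

Because no EEG recordings ship with the package, a first-class
synthetic generator (`generateSession`) produces sessions with
closed-form ground truth: AR(2) channels whose pole radius rises from
0.99 to 0.995 inside the intention interval (known τ via
`theoreticalTau`), a 10 Hz mu rhythm whose amplitude is halved after
onset (known -75% plateau ERD), tap events, and a seeded, bit-identical
layout.

## Worked example

```r
library(relaxEEG)

cfg    <- synthConfig(nTrialsPerCondition = 40,
                      conditions = c("right", "rest"), seed = 1)
ses    <- generateSession(cfg)                       # ~10 min of EEG, 9 channels
trials <- epochTrials(toBipolar(applyFilters(ses$recording)), ses$events)
tau    <- tauTimecourse(trials, lo = 0.5, hi = 30)   # wide-band tau features
fm     <- classificationFeatures(tau, "right", "tau_s")
curves <- sensitivityCurve(fm, cvScheme(seed = 1))
sel    <- selectBestChannel(curves, binomialThreshold(40))
str(sel$detection)
#> List of 5
#>  $ threshold          : num 0.65
#>  $ first_crossing_time: num -1
#>  $ peak_sensitivity   : num 0.741
#>  $ peak_time          : num 3
#>  $ channel            : chr "F3-C3"
```

The selected channel reaches a peak cross-validated sensitivity of
74.1% -- above the 65% chance threshold for 40 trials -- and first
crosses the threshold 1.0 s before the registered tap onset. On this
seed the nominal peak sits at the trial edge (a cross-validation noise
excursion; the curve also rises to 0.71 inside the intention window at
t = 0.5 s), which is why detection timing is judged on the
threshold-crossing time and, across seeds, on its average: over seeds
1-5 the mean first crossing is -0.66 s, i.e. detection before movement
onset (`scripts/acceptance.R` reports exactly this). Median window τ
rises from 0.125 s at rest to 0.172 s inside the intention interval,
against closed-form generator values of 0.097 s (rest pole) and
0.195 s (intention pole); the tap-vs-rest Welch test on per-trial onset
τ rejects at p < 1e-4.

`runPipeline(config, outDir)` chains all stages and writes TSV feature
tables, sensitivity curves, and JSON summaries;
`inst/cli/relaxeeg.R` exposes `simulate`, `run`, `preprocess`,
`classify`, `report` and `cohort` subcommands over the same functions
(EDF out/in, TSV events).

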