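---
title: "Microstate-segmented dynamic EEG networks and their spatiotemporal variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate-segmented dynamic EEG networks and their spatiotemporal variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msnetvar)
```

## The model

Resting EEG is modeled as a sequence of *microstates*: brief (tens of
milliseconds) epochs during which the scalp potential topography is
quasi-stable, drawn from a small set of template maps, conventionally four
(A–D). `msnetvar` uses this segmentation as the windowing rule for dynamic
functional-connectivity analysis, on the premise that a window aligned with
one transient brain state yields a more homogeneous — hence more
informative — network estimate than an arbitrary fixed window.

The pipeline has four statistical layers.

**Segmentation.** Global field power, the per-sample population standard
deviation of the potential across electrodes, marks moments of maximal
topographic signal-to-noise at its peaks. Peak maps are clustered with a
polarity-invariant ("modified") K-means: a map and its sign flip belong to
the same class, so assignment maximizes the squared spatial correlation to
a template, and the template update is the dominant eigenvector of the
assigned maps' (GFP²-weighted) outer-product sum rather than their mean.
Convergence is monitored by the global explained variance (GEV); the best
of `n_init` restarts is kept. Continuous data are then *backfit*: every
sample takes the class of maximal absolute spatial correlation, and runs
shorter than a minimum duration are merged into the better-correlated
neighbor.

**Connectivity.** Within every window the phase lag index
\(PLI_{ij} = |\langle \mathrm{sign}\,\sin(\phi_i - \phi_j)\rangle|\)
is computed from analytic-signal phases. PLI measures the *asymmetry* of
the phase-difference distribution: exactly-zero (or π) lags — the signature
of volume conduction — contribute nothing (sign(0) = 0), while a consistent
non-zero lag drives the index to 1. Three windowing schemes produce network
sequences: SN (fixed sliding windows), MN (microstate windows), MCN
(microstate windows partitioned by class).

**Variability.** For channel *i* over a sequence of *v* networks, temporal
variability \(T_i\) is one minus the mean Pearson correlation between the
channel's connection rows (diagonal removed) over all ordered window pairs;
spatial variability \(S_i\) is one minus the mean correlation between the
across-window time courses of the channel's individual connections, over
all ordered pairs of distinct partners. Both lie in [0, 2]; the ordered-pair
normalizers \(v(v-1)\) and \((n-1)(n-2)\) equal the unordered-pair means by
the symmetry of correlation (asserted in the tests). "Correlation
coefficient" is taken as Pearson's product-moment correlation.

**Inference.** Feature tables (per channel, T and S, per class for MCN) are
compared across schemes with one fixed classifier: a linear-kernel SVM,
cost 1, in stratified 5-fold cross-validation repeated 10 times (50
trials), features standardized with training-fold statistics only. Group
maps use pooled-variance t-tests (t is control minus patient, so negative
t = patient higher) with Benjamini–Hochberg FDR within each class ×
statistic map; whole-brain tables adjust across the four classes. Spearman
correlations (midranks, two-sided t-approximation p) relate variability to
clinical scores.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| band edges | 2–20 | Hz | standard broadband for microstate work; the filter is a zero-phase Hamming windowed-sinc FIR, order ≈ 3.3·fs so the transition band is about 1 Hz at 500 Hz |
| `k` (classes) | 4 | – | the canonical A–D set; configurable |
| GFP peak `min_distance` | 10 | ms | keeps clustered maps locally independent; no published value exists, so it is an explicit convention |
| `smooth_min_duration` | 20 | ms | runs shorter than a microstate's plausible lifetime are relabeling noise; merging uses the better-correlated neighbor; 0 disables |
| `min_window` | 5 | samples | PLI needs several samples; shorter microstate windows are skipped and counted, never silently padded |
| SVM | linear, cost 1 | – | a fixed, weak learner so that accuracy differences reflect the feature sets, not tuning; standardization is an addition made explicit because SVMs are scale-sensitive |
| FDR family | per class × statistic map | – | the natural "one topographic map" family; a global family is available as a configuration |

## The synthetic generator

`generate_recording()` encodes exactly the statistical structure the
measures assume, nothing more:

- **Templates.** One shared set per cohort — microstate maps are canonical
  across people, and shared templates are what make class identities
  comparable between subjects. The default set takes the canonical A–D
  shapes built from 10–20 electrode geometry and blends them toward their
  Gram–Schmidt orthogonalization until all pairwise |spatial correlations|
  are ≤ 0.5 (the literal canonical shapes share the anterior–posterior
  gradient at r ≈ 0.7, which would make recovery experiments ill-posed).
  Each subject adds small Gaussian topographic jitter.
- **State sequence.** Exponential-like dwell times around 60 ms (truncated
  at 2 samples), never repeating the same state consecutively.
- **Signals.** Within a state window, channel *i* is its template weight
  times \(\cos(\Phi(t) + \theta_i)\): a shared band-limited carrier (5–14 Hz,
  random-walk phase jitter) with per-channel lags. At GFP peaks the map is
  proportional to the template (what segmentation recovers); the pairwise
  lag differences \(\theta_i - \theta_j\) set each pair's PLI (what the
  network stage recovers). The lag vector is the state's *coupling
  pattern*; it is redrawn at the class's switching rate, with quasi-regular
  pattern lifetimes (1/rate ± 25 %) reflecting the slow, sustained
  reconfiguration timescale reported for dynamic functional connectivity.
  Defaults: 19 channels, 500 Hz, 60 ms dwell, amplitude SNR 10 against
  white noise, lag spread 0.8 rad, switching rate 0.033 patterns/s
  (≈ 30 s pattern lifetimes).
- **Group effects** multiply class-specific switching rates (and,
  optionally, shrink a class's lag spread as a "synchrony" effect). Higher
  switching produces higher temporal variability of that class's networks
  — the causal chain the analysis is supposed to detect.
- **Designing class-specific injections.** An injection that raises one
  class's switching rate without compensating elsewhere also raises the
  *total* pattern turnover — a global effect that class-blind sliding-window
  features can legitimately detect. Experiments meant to isolate the value
  of class resolution therefore use class-balanced injections whose
  multipliers sum to the number of classes (e.g. A ×0.75, B ×2, C ×0.5,
  D ×0.75): total turnover is matched between groups and only
  class-resolved features carry the contrast. Effect-direction experiments,
  whose target is the sign pattern of specific classes rather than scheme
  comparison, use the unbalanced pair (B ×2, C ×0.5) directly.
- **Clinical scores.** Patients receive synthetic UPDRS-III and MoCA values
  through a stated linear link: each score is an affine function of the
  subject's standardized realized log switching rate (class B for the motor
  score, class C for cognition) plus Gaussian noise, so Spearman-recovery
  analyses have a known monotone target.

What the generator does *not* emulate: volume conduction with realistic
head geometry, 1/f background spectra, artifacts (ocular, muscle), non-
stationary state prevalence, or correlated noise across channels. Passing
tests therefore demonstrate that the estimators recover the structure they
are defined on — not that clinical effect sizes on real EEG will be
comparable.

## Numerical choices and degenerate inputs

- Spatial correlation centers maps across channels, so it equals the cosine
  of centered vectors; flat (zero-variance) samples are unassignable and
  carry an `NA` sentinel excluded from windows.
- Empty clusters during K-means are re-seeded from the worst-fit map; ties
  in assignment go to the first template.
- `sign(0) = 0` in the PLI, so identical signals score exactly 0.
- Degenerate variability inputs (a constant connection row within a window,
  a constant connection time course across windows) raise errors naming the
  offender in the strict operations. The profile layer offers an explicit
  `drop_degenerate` mode — used by the cohort pipeline — that drops
  saturated windows and excludes constant connection time courses from the
  spatial average, always with a count in a warning; silent zero-correlation
  substitution is never performed because it would bias group statistics.
- Classes with fewer than two usable windows are reported as missing, and
  subjects with missing class features are dropped (default) or
  mean-imputed, with provenance recorded in the feature table.
- SN windows that would overrun the recording are dropped, not padded.

## Open design points, resolved

- *Analysis reference*: acquisition used earlobe references; the analysis
  re-references to the common average before topographic clustering, the
  standard choice when none is stated.
- *Templates per group or shared*: both are supported; per-group fitting is
  the default to mirror the two-group clinical design, with canonical A–D
  ordering giving classes comparable identities across groups.
- *Smoothing before window construction*: applied by default (20 ms) since
  unsmoothed backfitting fragments windows below PLI-usable lengths; it is
  configurable and can be disabled.
- *Phase extraction*: the analytic signal on the band-passed data, the
  construction under which the PLI was defined.

## Simulation sizes used in the tests

The test suite runs desk-scale versions of each experiment, chosen as the
smallest sizes at which the estimators' behavior is stable: recovery
experiments use 120-s recordings over 20 seeds; scheme-ordering cohorts use
20 subjects per group with 60-s recordings over 10 seeds; effect-direction
cohorts use 10 subjects per group with 60-s recordings over 20 seeds;
calibration nulls use 10 000 replicates. Cohort analyses pass
`min_window = 10` samples (20 ms) because the shortest microstate windows
yield PLI estimates too coarse to carry pattern information, and
`n_init = 5` restarts, which is ample for four well-separated templates.

## Known limitations

- The variability statistics are undefined for classes that occur rarely;
  subjects missing a class propagate as missing values by design.
- PLI over tens-of-milliseconds windows is a coarse estimator (quantized at
  1/m); group-level contrasts rely on averaging over many windows.
- The SVM harness deliberately omits hyperparameter search, feature
  selection and nested cross-validation; it is a comparison instrument, not
  a production classifier.
- EDF support covers continuous equal-rate 16-bit recordings only.
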