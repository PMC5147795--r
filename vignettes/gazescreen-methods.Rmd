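---
title: "Methods: event detection, the 168-feature taxonomy and the screening protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event detection, the 168-feature taxonomy and the screening protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazescreen)
```

## The problem

`gazescreen` analyses binocular gaze recordings of children silently
reading a short multi-line text, and asks whether the oculomotor record
alone can separate high-risk (HR) readers — children with early,
persistent word-decoding difficulties — from low-risk (LR) controls. The
pipeline has four stages: (1) segment the 100 Hz binocular signal into
eye-movement events with a dynamic dispersion-threshold state machine;
(2) summarise the events into a fixed 168-dimensional feature vector per
subject; (3) estimate HR/LR discriminability with a linear
support-vector machine under recursive feature elimination (SVM-RFE),
evaluated by repeated stratified cross-validation with fold-internal
feature selection; (4) analyse which features carry the signal. Because
no public cohort of this kind exists, the package ships a seeded
synthetic-cohort generator whose recordings have the statistical
structure the analysis assumes; every stage is exercised against it.

## Signals and coordinates

Positions are degrees of visual angle; x increases rightward, y
downward (text lines progress to larger y), origin at the start of the
first line. The two eyes are decomposed into the conjugate and
disconjugate components per axis:

* version = (left + right) / 2 — where the eyes point together;
* vergence = left − right — their disconjugacy.

A sample with either eye invalid is unusable in all four series. The
detector runs on the version signal only; vergence is carried along for
feature computation. The generator applies its vergence offset
antisymmetrically (±offset/2 per eye), so the version signal equals the
simulated cyclopean trajectory exactly — this is what makes exact
ground-truth recovery a meaningful test.

## The dispersion-threshold state machine

The detector walks the recording sample by sample through four mutually
exclusive states — distortion, transient, fixation, saccade — under a
dynamic threshold

> T = `dispersion_base` + `noise_multiplier` × RMS noise,

with defaults 0.5° and 2.5. The 0.5° base reflects the extent of the
foveal field; the noise term adapts the criterion to the momentary
signal quality.

* **Distortion**: the binocular signal is missing (both eyes, or either
  eye of the averaged pair). A distortion interrupts the current run;
  the interrupted run is emitted as-is and never merged across the gap.
* **Stable (transient → fixation)**: a usable sample whose horizontal
  *and* vertical version positions are within T of the running mean of
  the current stable run extends the run; a run is promoted from
  transient to fixation once its inclusive time span reaches
  `min_fixation` = 50 ms (six samples at 100 Hz, since a span of n
  samples covers (n−1) × 10 ms). A sample exactly at distance T counts
  as within.
* **Saccade**: a sample beyond T on either axis opens a saccade. While
  a saccade is in flight, each incoming sample is compared with the
  saccade's most recent position; the first sample that lands within
  threshold of the previous one closes the saccade and seeds a new
  stable run. The comparison is deliberately local: a running mean of
  in-flight samples lags mid-trajectory and would systematically delay
  every fixation onset, which is observable as a failure to recover the
  generator's ground-truth boundaries in the noiseless limit.

**Noise estimation.** The RMS noise is the root-mean-square deviation
from the window mean of the last `noise_window` = 25 samples *of the
current stable run*, and is frozen at the last stable run's value while
a saccade is in flight. A raw trailing window would include in-flight
samples, inflating T mid-saccade and destroying boundary recovery; run
scoping keeps the estimate a measure of stationary noise around
fixation, which is what the threshold is meant to adapt to. At the start
of a run (fewer than two samples) the estimate is 0 and T equals the
base.

**Directions.** Saccades with positive horizontal displacement are
progressive, negative regressive, except leftward movements of at least
`sweep_min_amplitude` = 5° which are sweeps (most commonly return
sweeps) with no direction. Displacement is anchored at the last usable
position before the movement began: single-sample saccades otherwise
have zero within-event displacement. Fixations inherit the direction of
the nearest preceding saccade; after a sweep the following fixation is
progressive (reading resumes forward on the new line); an opening
fixation with no preceding movement has no direction and joins no
directional feature pool.

**A property that does not hold globally.** Raising `dispersion_base`
never adds saccades at or above the default threshold, and this is
tested. Strictly below the measurement-noise floor the relationship
inverts: near-zero thresholds keep consecutive noisy samples in one long
saccade run, so *fewer*, longer saccade events are emitted. This is
intrinsic to any sample-by-sample dispersion machine, not an
implementation artifact.

## The 168-feature taxonomy

Events are pooled into four classes — progressive/regressive fixations
and saccades (PF, RF, PS, RS); sweeps, transients, distortions and
direction-less fixations contribute to no pool. Each event yields its
duration (Dur, ms) and, for each of the four signals (horizontal and
vertical version and vergence), five spatial parameters:

| code | meaning |
|------|---------|
| D | spanning distance, signed: last − first position |
| M | mean position |
| S | population SD of position within the event |
| R | maximum range between any two positions |
| A | accumulated distance over all subsequent positions |

Within each pool, each parameter's distribution over events is
summarised by its mean and population SD. The count is
4 × (1 + 5×2×2) × 2 = 168, and for every event and signal
A ≥ R ≥ |D| ≥ 0.

Three readings were fixed where the taxonomy description leaves room:
the "standard deviation of the average position" is the within-event SD
of position (the event's mean position is a single number, so its SD can
only refer to within-event dispersion); D is kept signed, retaining
direction information (documented so users can take absolute values
downstream); population rather than sample SD is used both within events
and across pools, because it is well-defined for single-element pools.
Empty pools are zero-filled and flagged rather than set missing, keeping
the classifier input rectangular while letting analyses audit the
imputation.

## The evaluation protocol

Discriminability is estimated with linear SVMs (soft-margin cost C = 1,
libsvm's SMO solver via `e1071`) under 10-fold stratified
cross-validation repeated a number of times with fresh random splits
(100 repetitions is the documented full configuration; the package's
test suite runs 10 at cohort scale and fewer in unit tests). The
non-negotiable structural rule is that *everything fitted is fitted
inside the training fold*: z-score standardization uses training-fold
statistics only, and feature selection is rerun in its entirety inside
every training fold. Selection performed once on the full data before
splitting is the classic leakage that inflates cross-validated accuracy.

* **SVM-RFE** ranks features by squared primal weight, removing exactly
  one lowest-weight feature per refit until none remain; the ranking is
  the reverse elimination order. Exact weight ties are broken by
  removing the larger column index, making the ranking deterministic.
  Standardization is what makes weight magnitudes comparable across
  features.
* **Random selection** draws n features uniformly in each training fold
  — the baseline that separates the value of *ranking* from the value
  of *shrinking* the feature set.
* **Y-randomization** flips the labels of half the subjects of each
  class (⌊n/2⌋ each, at random) in the training fold only, leaving test
  labels untouched: the chance-level null.

Per repetition, test predictions are pooled over the ten folds (every
subject is tested exactly once), and metrics are reported as mean ± SD
over repetitions. HR is the positive class: sensitivity is the
proportion of HR subjects identified, specificity the proportion of LR
subjects excluded. Paired classifier comparisons over the repetitions
use the variance-corrected resampled t-test,
t = mean(d) / sqrt((1/k + ρ) var(d)) with ρ = test_fraction/(1 −
test_fraction) and k − 1 degrees of freedom — the correction accounts
for the overlap of training sets across resamples, and can only shrink
|t| relative to the naive paired test.

C and the standardization choice are config-exposed
(`trainer_config()`); results on real data could shift with them.

## Feature analysis

For RFE runs, selection frequency counts how often each feature appears
in the top-n over all folds × repetitions training folds. Summaries use
linear-interpolation quartiles (R's type 7); "selected in the majority
of folds" means strictly more than half. The hierarchical breakdown
tallies accumulated frequency down event class → axis → binocular mode →
parameter for spatial features, with duration broken out in a separate
temporal tree, and frequency is conserved at every level. Group
contrasts are displayed after min-max normalization over both groups
pooled — per-group normalization would erase exactly the contrast of
interest.

## The synthetic-cohort generator

The generator emulates the study conditions: 97 HR and 88 LR subjects,
100 Hz binocular sampling, silent reading of an 8-line passage of 10
sentences averaging 4.6 words (46 tokens, 33 types: TTR 71.7%, OVIX 46,
OVR 91.3%, computed with natural logarithms, which reproduce all three
printed values), recordings under a minute.

A recording is a piecewise trajectory over the line geometry (20° line
extent, 1.5° spacing — a single page at 45 cm):

* fixation durations: log-normal, HR 280 ± 70 ms vs LR 210 ± 50 ms;
* progressive saccade amplitudes: gamma, HR 2.0 ± 0.8° vs LR
  3.0 ± 0.9°, truncated below at 1.0° (smaller movements are not
  resolvable against a 0.5° dispersion threshold at 100 Hz);
* regressions with probability 0.35 (HR) vs 0.15 (LR), leftward, about
  60% of the progressive amplitude;
* return sweeps at line ends: leftward by the line extent, down one
  spacing.

These group contrasts are plumbing defaults oriented by the direction of
known HR/LR differences (longer fixations, shorter forward saccades,
more regressions in struggling readers); they are config-exposed, not
empirical claims. Saccades are rendered as a constant-velocity ramp of
1–4 in-flight samples with a fixed 0.4° deceleration gap before landing.
A minimum-jerk profile was considered and rejected: its first and last
steps fall below the 0.5° threshold, so no dispersion detector could
recover the rendered boundaries exactly, and boundary-exact recovery in
the noiseless limit is the package's strongest correctness oracle.

On top of the trajectory: an AR(1) vergence offset (φ = 0.95, SD 0.20°
HR / 0.15° LR, split ±half per eye), white per-eye measurement noise
(SD 0.05°, near the Ober-2-class resolution of 5 arcmin), both-eye
dropouts (probability 0.002/sample) and short 2–5° common-mode transient
artifacts (0.1/s). Each subject's duration and amplitude means (and, on
the logit scale, regression probability) are jittered with a
between-subject coefficient of variation of 0.12 — without
between-subject variability all subjects of a group would be
near-identical and the classification task degenerate.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: no lexical content (no word-frequency or
landing-position effects), no microsaccades, smooth pursuit or
physiological blinks, no head movement, no calibration drift, and
group-conditional distributions that are cleaner and better separated
than real oculomotor populations. Accuracies on synthetic cohorts
validate the protocol's machinery (leakage-free selection, chance-level
nulls, ranking validity), not the clinical effect size.

## Problem sizes and numerical choices

The test suite runs the full pipeline at cohort scale (185 subjects, 10
protocol repetitions, a 7-point feature-size grid) plus noiseless-oracle
and invariant checks over 100 seeded recordings; unit tests use cohorts
of 8–28 subjects and 2–5 repetitions. The RFE-validity fixture uses 4
informative + 32 noise features with the informative features arranged
as two jointly necessary pairs (class signal masked by a shared nuisance
only the pair cancels): independently shifted copies are mutually
redundant, and recursive elimination legitimately discards redundant
copies, so joint necessity is the construction that tests ranking
validity rather than redundancy handling.

Other numerical conventions: seeds fan out to per-subject and per-fold
child seeds through a fixed affine map, so any element of a run can be
regenerated in isolation; constant features standardize to zero rather
than NaN; quantiles are type 7 throughout; a recording shorter than the
minimum fixation span yields an empty event list with a warning; a
subject with no directional fixations and saccades yields an all-zero,
fully flagged feature vector.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_hr = 14, n_lr = 14, seed = 301, duration_cap = 20)
feats <- cohort_features(generate_cohort(spec))
res <- run_protocol(as.matrix(feats[, feature_schema()$id]), feats$label,
                    protocol_config(folds = 5, repetitions = 5,
                                    n_features_grid = c(8, 32, 168),
                                    seed = 7))
summary(res)
freq <- selection_frequencies(res)
frequency_summary(freq)
```

## Known limitations

Real recordings differ from the generator in every way listed above, so
thresholds tuned here (sweep amplitude, dispersion base) should be
revisited on real data. The dispersion machine has no velocity model, so
very slow drifts can masquerade as fixation and the transient class
conflates short stable periods with recovery from artifacts. The SMO
cost, tolerance and standardization are not identifiable from the
screening-study description; conclusions that depend on them should be
checked over a small grid. Sensitivity/specificity pooling
(pooled-per-repetition, then averaged) is one of two defensible
conventions and is stated rather than assumed silently.
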