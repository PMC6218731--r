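---
title: "Estimating blood pressure from PPG pulse morphology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood pressure from PPG pulse morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The problem

A photoplethysmogram (PPG) is the optical blood-volume waveform measured at
the fingertip, one pulse per heartbeat.  Because the shape of that pulse is
modulated by arterial pressure and vascular tone, a single PPG sensor is an
attractive basis for *cuffless* blood-pressure estimation: no
electrocardiogram, no second sensor for transit-time measurements, and no
inflating cuff.  `ppgbp` implements a complete, testable version of the
morphology-only approach: 5 s PPG segments are screened, preprocessed into
per-beat normalized pulses, summarized by five shape features, reduced to
three features by a multicollinearity filter, and fed to three regression
learners whose cross-validated estimates are judged against the reference
cuff pressures with Bland–Altman agreement statistics and an ISO-style
accuracy verdict (mean difference within 5 mmHg, SD within 8 mmHg).

Because the clinical recordings that motivate this design are not
redistributable, the package ships two substitutes that make every stage
verifiable:

* a **synthetic PPG generator** whose pulses are deterministically linked to
  known ("true") systolic and diastolic pressures, and
* the **published per-case result tables** of a 32-case clinical evaluation
  of the same pipeline, transcribed as plain-text fixtures, so the agreement
  arithmetic can be checked against printed clinical numbers.

## Pipeline and models

### Preprocessing

Each accepted 5 s segment (500 samples at 100 Hz) passes through:

1. **Savitzky–Golay smoothing** (`sg_smooth`), 4th order, 19-sample frame.
   The filter is a moving least-squares polynomial fit; it reproduces
   polynomials up to degree 4 exactly (a property the tests assert) and
   preserves sharp systolic edges better than a plain moving average.
   Smoothing is used for *delineation* — peak picking and foot placement —
   not for morphology measurement: at 100 Hz the 19-sample window displaces
   an asymmetric systolic peak by 1–2 samples, which would bias the rising
   time, so beats are cut from the raw detrended signal.
2. **Beat detection** (`detect_beats`): adaptive-threshold peak picking
   (half the local signal range over a 2 s rolling window) with a 0.3 s
   refractory period, then foot placement at the signal minimum in a window
   anchored just before each systolic upstroke.  Anchoring on the upstroke
   keeps respiratory wander and shallow diastolic tails from dragging feet
   away from the true beat onset; a rolling-mean rough baseline (one beat
   period, reflected at the segment edges) is subtracted before the minima
   are located.
3. **Baseline removal** (`remove_baseline`): the piecewise-linear
   interpolant through the foot samples is subtracted, pinning every foot
   to zero.  This removes sub-Hz respiratory wander exactly where it
   matters without distorting within-beat morphology, and is exactly
   testable (a linear drift is removed identically).
4. **Two-dimensional normalization** (`normalize_pulse`): every complete
   beat is resampled by linear interpolation onto N = 100 points over
   normalized time [0, 1] and rescaled so its minimum is exactly 0 and its
   maximum exactly 1.  The first and last beat of a segment are discarded
   (their outer feet border truncated beats), as is any beat whose duration
   deviates more than 15% from the segment median.

### Features

Five dimensionless features are computed per beat and averaged over the
segment's complete beats (the reference cuff pressure is constant over the
5 s window, so one feature vector per segment is the natural unit):

* **pulse area** — trapezoidal integral of the normalized pulse;
* **rising time** (crest time) — normalized time of the first sample
  attaining the peak;
* **width at 25/50/75%** — time spent above each fractional amplitude,
  measured from the *first* up-crossing to the *last* down-crossing with
  linearly interpolated crossings.  Using the outermost crossings means a
  dicrotic wave that re-crosses a level widens the measurement rather than
  splitting it, which matches how the width of a whole pulse is read off a
  plot.

The three fractional widths measure nearly the same underlying quantity, so
they are strongly collinear.  `select_features` applies the standard
variance-inflation-factor filter: `VIF_j = 1/(1 - R²_j)` from regressing
feature j on the others; while any VIF exceeds 10, the worst offender is
dropped (ties go to the later column) and the VIFs are recomputed.  On both
the synthetic data and, reportedly, on clinical data this eliminates
`width_50` and `width_75` and retains `area`, `rising_time`, `width_25`.

### Learners

All three learners are fitted independently for SBP and DBP on the three
selected features.

* **Multiple linear regression** (`fit_mlr`): ordinary least squares with
  intercept, solved in closed form by QR decomposition.  The iterative
  least-squares description often given for this model converges to the
  same optimum; the closed form is exactly testable against the normal
  equations.
* **Linear ε-SVR** (`fit_svr`): support vector regression with the linear
  kernel and ε-insensitive (L1) loss.  The dual is solved by an SMO-style
  maximal-violating-pair method; convergence is declared only when the
  normalized primal–dual feasibility gap Δ = (J(β) + L(α))/(J(β) + 1)
  falls below the gap tolerance (default 1e-3), and the final gap is stored
  on the model.  Defaults: ε = 2 mmHg (the tube half-width must live on the
  response scale), C = 1 on internally standardized features (so the box
  constraint is comparable across features), with the standardization
  constants kept on the model.  The tests check the solver against an exact
  enumeration of KKT states on tiny problems and against an independent
  implementation.
* **CART regression tree** (`fit_tree`): greedy binary recursive
  partitioning.  Candidate thresholds are midpoints between adjacent sorted
  feature values; each split minimizes the summed child squared error; a
  node is declared pure — and left unsplit — when its response MSE falls
  below the whole-sample MSE times a tolerance (default 1e-4), with growth
  further limited by a maximum depth (12) and a minimum leaf size (5).
  Leaves predict the exact arithmetic mean of their training responses.
  Ties between equally good splits go to the lowest feature index, then
  the smallest threshold, so trees are bit-reproducible.  At prediction
  time a value equal to a threshold is routed right; thresholds are
  midpoints, so this can only occur on unseen data.

### Evaluation

`kfold_assign` permutes the segments under a seed and deals them
round-robin into k = 10 folds (sizes differ by at most one; 8133 segments
give three folds of 814 and seven of 813).  `cross_validate` trains on nine
folds and predicts the held-out fold, so every segment receives exactly one
out-of-fold estimate per target.  Fold assignment is segment-level by
design — the clinical protocol pooled all segments before splitting — so
estimates for a case's segments may come from models that saw that case's
other segments; this is a property of the protocol being replicated, not an
accident.

Per-case aggregation (`per_case_summary`) averages reference and estimated
pressures over each case's qualifying segments and takes the difference
(reference − estimate).  Stratified summaries use the *reference* BP
category of each segment: hypertensive when SBP ≥ 140 or DBP ≥ 90 mmHg,
otherwise hypotensive when SBP < 90, otherwise normotensive.  Diastolic
pressure is deliberately not part of the hypotensive rule because clinically
normotensive monitor readings reach diastolic values in the low 40s.  All
four thresholds are configurable.  `difference_stats` uses the n−1 sample
SD (the population SD does not reproduce the printed SD of the packaged
clinical differences; the sample SD does).  `bland_altman` reports
bias ± 1.96 SD limits, and `iso_check` applies the accuracy criterion
|mean| ≤ 5 mmHg and SD ≤ 8 mmHg, boundaries inclusive.  Display rounding is
one decimal, half away from zero, as in clinical tables.

## The synthetic generator

`generate_dataset` emulates the data a bedside monitor would deliver: for
each simulated case, per-category blood-pressure anchors, a heart rate
(55–95 beats/min) and an amplitude gain are drawn; each 5 s segment then
draws a category from the configured mix (80/12/8% by default), jitters the
case anchor by 1.5 mmHg, and synthesizes a beat train at 100 Hz with
respiratory baseline wander (0.25 Hz sine, 20% of pulse amplitude),
additive Gaussian sensor noise (0.8% of pulse amplitude — bedside PPG after
quality screening is a clean signal), and, for a random 5% of segments, an
injected artifact (a saturation plateau at the signal ceiling or a dropout
below its floor).  Thirty-two cases of 50 segments each are generated by
default, mirroring a 32-case clinical recording campaign at a size that
keeps the full pipeline fast.

### Beat model

Each beat on normalized time u ∈ [0, 1) is the sum of

* a two-sided Gaussian **systolic wave** — rising σ = r/5 (so the rising
  limb vanishes at the foot), steep falling σ solved from the width target;
* a **dicrotic wave** (Gaussian bump) whose height is about a third of the
  systolic amplitude and decreases with SBP (stiffer vessels attenuate the
  reflected wave), positioned so that the combined curve re-crosses the 25%
  level at a controlled point beyond the systolic envelope;
* a low diastolic **runoff pedestal** (a capped ramp, zero at both beat
  boundaries) that gives every beat a sharp V-shaped foot, as diastolic
  runoff does in real PPG.

The link from blood pressure to shape is an invertible *linear morphology
map*: rising time decreases linearly with SBP, width-25 increases linearly
with DBP, and area is tied (weakly) to both; the default coefficients keep
all shapes feasible for SBP ∈ [70, 190] and DBP ∈ [40, 100] mmHg.  No
quantitative shape–pressure law of this form is established physiology; the
map is a modelling stand-in for the qualitative associations (earlier,
steeper pulses at higher systolic pressure; broader pulses at higher
diastolic pressure), chosen to make parameter recovery exactly checkable.

Three solver details matter for testability:

* the **width target is hit through the dicrotic extension**: the systolic
  envelope's 25% crossing is placed at the map value minus a mean extension
  (0.04 + 0.15 × width), and the dicrotic wave's position supplies the
  rest.  Per-segment width variability (SD 0.014) therefore moves only the
  outermost 25% width; the 50% and 75% widths are geometric consequences of
  the systolic wave alone.  This reproduces a structure real pulses have —
  the base width carries information (dicrotic timing, runoff) that the
  crest widths do not — and it is what makes the VIF filter behave as on
  clinical data: `width_50` and `width_75` are mutually near-redundant
  (VIF ≫ 10) while `width_25` retains enough private variation to survive.
* the **area target is absorbed by the pedestal height** (1–9% of
  amplitude), which changes the area while leaving the fractional widths
  essentially untouched; per-segment area jitter (SD 0.009) keeps area from
  being a linear function of the other retained features.
* the generator stores, per segment, the **realized morphology** of its
  analytic beat (measured on a 2001-point grid with the same feature
  definitions the pipeline uses), so extraction accuracy can be asserted
  against ground truth rather than against the map.

Sensor noise and artifacts are drawn from a per-segment sub-stream whose
seed is itself drawn from the main stream: two configurations differing
only in noise, wander or artifact settings share identical latent pressures
and morphology, which is what makes clean/noisy paired comparisons and the
noise-free acceptance runs meaningful.

### What the generator does not emulate

Pulse-shape dynamics within a segment (every beat in a segment shares one
morphology), beat-to-beat heart-rate variability beyond small jitter,
motion artifacts more complex than plateaus and dropouts, sensor-specific
transfer functions, and — most importantly — any *true* physiological
shape–pressure relationship.  A pipeline that passes the parameter-recovery
tests here is demonstrated to be internally correct (it can read back what
the generator wrote); that is a prerequisite for, not evidence of, accuracy
on real patients.

## Numerical choices and degenerate inputs

* Rising-time resolution is bounded by the 100 Hz raw grid (~1 sample,
  i.e. ~0.01–0.015 of a beat), not by the N = 100 resample: the argmax of a
  linearly interpolated resample falls on a raw sample.  Width crossings
  interpolate between samples and recover to ~0.003.
* Quality screening (`assess_quality`) reports *all* violated rules:
  missing reference pressures, flatline (SD below 1e-6 of the range),
  clipping (25+ consecutive samples at the segment maximum or minimum),
  and implausible beat count (outside 3–15 per 5 s).  Relaxing any single
  threshold can only grow the accepted set.
* A segment whose beats all fail the duration filter falls back to its
  single most regular interior beat rather than erroring, so rare
  wander/noise configurations do not abort a batch run.
* Perfect collinearity reports VIF = +∞ rather than failing, and the
  selection loop then applies its usual largest-VIF/later-column rule.
* The SMO solver treats a numerically blocked best pair by trying the next
  few top-ranked violating pairs before concluding it is finished; the
  feasibility gap is always evaluated with the exactly-optimal bias (the
  knot of the piecewise-linear slack where the subderivative changes sign).

## Problem sizes

The packaged tests and the acceptance script use 32 cases × 50 segments
(1600 segments) for the default-condition runs and 20 cases × 50 segments
for the noise-free recovery runs — large enough that category proportions,
VIF estimates and per-case agreement statistics are stable, while a full
end-to-end run stays near a minute on a single core.  All sizes are
configuration fields, and the generator scales linearly in segments.

## Known limitations

* The morphology map is linear and noise-free by construction; real
  shape–pressure coupling is nonlinear, subject-specific and confounded by
  age, arterial stiffness and vasoactive state.
* Fold assignment at segment level means cross-validated accuracy on
  synthetic data should be read as *protocol replication*, not as an
  estimate of accuracy on unseen subjects; a case-grouped assignment would
  be the stricter design.
* The ISO-style verdict used here is the simple two-number criterion
  (|mean| ≤ 5, SD ≤ 8 mmHg); the full device-validation standard contains
  additional requirements (subject counts, cuff procedures, per-subject
  tolerances) that are out of scope.
* The quality screen is a rule-based stand-in for visual review; it is
  deliberately conservative and configurable, and it makes no attempt to
  reproduce any particular clinical screening decision.
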