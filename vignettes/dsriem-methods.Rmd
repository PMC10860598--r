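---
title: "Models and methods behind dsriem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dsriem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsriem)
```

`dsriem` analyses dual-serial-retrocue (DSR) working-memory fMRI
experiments in which two sample stimuli, each defined by a polar-angle
location and a bar orientation, are memorized; a first retrocue (the
orientation of one item) prioritizes one item for the first recognition
probe, and a second retrocue either stays with or switches priority before
a second probe. Location is the to-be-reported *content*; orientation is
the *context* used to cue priority. The scientific question the pipeline
serves is whether early visual cortex and intraparietal sulcus represent
these features according to their *domain* (orientation vs location),
their *function* (content vs context), or a *hybrid* of the two — each
account predicting a distinct pattern of positive, null, and negative
reconstruction slopes for the prioritized and unprioritized items (PMI,
UMI) at the end of the post-cue delay.

This vignette records the models, conventions, and numerical choices, and
what the synthetic-data tests do and do not establish.

## Trial design

The schedule crosses 9 signed location distances ({−160, …, 0, …, +160}°,
steps of 40°), 6 signed orientation distances ({−60, −30, 0, +30, +60,
+90}°), and the second cue's stay/switch status: 108 unique trial types,
each repeated 3 times for 324 trials, dealt into 27 runs of 12. The
crossing makes the same-orientation proportion exactly 1/6 and the
same-location proportion exactly 1/9 — these are also the context and
content load-of-1 proportions. Sample 1's features are drawn uniformly from
the 9 base angles (20°–340°) and 6 base orientations (15°–165°); sample 2
sits at the cell's signed distances. A location jitter, shared by both
samples and uniform on [0°, 10°], covers the circular space.

Epoch durations (s): sample 2, delay 1.1 8, cue 1 2, delay 1.2 8, probe 1
2.5, delay 2.1 1, cue 2 2, delay 2.2 2, probe 2 2.5. Probe 2's duration is
not independently specified in the task description; setting it equal to
probe 1 makes each trial 30 s, and with the mean 8-s ITI and four 2-s
dummy TRs each run lasts exactly 464 s, the run length the task timing
implies.
Two further conventions were genuinely open and are fixed as follows: ITIs
(6/8/10 s) are balanced *within* each run (four of each), so all runs have
identical duration rather than only the session mean; and the first cue is
near-balanced within each 3-trial cell (alternating items, with the odd
repetition assigned to item 1 in a random half of the cells), which makes
the global split exactly 162/162. Signed distances follow the convention
sample 2 − sample 1, wrapped to (−period/2, period/2].

## Channel basis

Each feature space carries equally spaced tuning channels whose idealized
response is a half-wave-rectified sinusoid raised to a power: activation
= max(0, cos(πΔ/P))^p, with Δ the signed circular difference between the
feature and the channel center, P the period (360° for location, 180° for
orientation), and p = 8 (location, 9 channels at 20°, 60°, …, 340°) or
p = 6 (orientation, 6 channels at 15°, 45°, …, 165°). The argument scaling
is chosen so one half-cycle of the rectified sinusoid spans the full
period — the standard encoding-model convention, under which activation is
1 at the center and falls to 0 at half a period; the compact sin^p notation
common in this literature leaves the scaling implicit. Channel centers coincide with the stimulus
base values; no iteration over basis phases is performed. For on-grid
features the activations across channels sum to a constant (a discrete
partition property), which is both asserted in tests and relevant to a
degeneracy discussed below.

## Encoding model, inversion, cross-validation

Voxel responses are modeled as weighted sums of channel responses,
B₁ = W C₁. Training solves the least-squares problem in closed form,
Ŵ = B₁C₁ᵀ(C₁C₁ᵀ)⁻¹ (v voxels × k channels), and inversion on held-out data
is Ĉ₂ = (ŴᵀŴ)⁻¹ŴᵀB₂. Both steps verify conditioning (reciprocal condition
number ≥ 1e−10) and fail loudly on rank-deficient inputs — for example
when all training trials share one feature value. The suite checks both
closed forms against a generic QR solver to 1e−8 on random instances.

Cross-validation is leave-one-run-out: for each TR, weights are estimated
from all runs but one at that TR (training labels are always the PMI's
feature) and inverted on the held-out run at the same TR, so every trial is
reconstructed exactly once. Each trial's reconstruction is then circularly
shifted by an integer number of channels so the channel nearest the test
item's label (PMI or UMI) lands at the common 0° position; sub-channel
jitter is ignored, as recentering to a channel grid implies. Reconstructions
are recentered before averaging; because the slope statistic is linear,
recenter-then-average and the reverse order give the same mean-curve slope.

Preprocessing contracts: per-run z-scoring of each voxel (the standard
preparation) and optional polynomial detrending (orders 1–3) are explicit
dataset-level steps, so the estimator itself is preprocessing-agnostic.

## The slope statistic and inference

A recentered curve is collapsed by averaging channels with equal absolute
offset; the unpaired half-period channel of the orientation basis (+90°)
enters as its own point. Collapsed values, ordered from the farthest offset
to the center (ranks 0, 1, 2, …), are regressed on rank: a center-peaked
reconstruction gives a positive slope, a center-inverted (remapped) one a
negative slope, and the magnitude indexes precision. The rank direction is
fixed by the convention that intact codes are reported as positive slopes.

Group inference resamples subjects with replacement, averages the resampled
curves, and recomputes the slope (10,000 iterations by default); the
two-tailed p is twice the smaller of the proportions of positive and
negative bootstrap slopes. By linearity the slope of an average equals the
average of slopes, so resampling is done on per-subject slopes — an exact,
much faster equivalent that a test verifies against the literal path. When
one sign is entirely absent the p value is reported at its resolution bound
2/B and flagged; an all-zero bootstrap distribution (identical inputs)
reports p = 1 as "no evidence". The PMI−UMI contrast resamples subjects
once per iteration and differences the two mean slopes. Sign-flip
permutation tests (for load contrasts) include the observed permutation and
report the proportion of permuted |mean| at least as large as observed.
FDR correction is Benjamini–Hochberg; time-course traces are corrected
across TRs within each ROI × dimension × item trace, and the eight
preregistered cells across cells.

The percentile bootstrap on a mean is mildly liberal at small cohort sizes
(its implicit cutoff at n = 24 is ≈1.92 rather than t₀.₉₇₅,₂₃ ≈ 2.07, an
empirical level near 0.067). The type-I calibration check therefore runs at
cohort size 100, where the test attains its nominal level; users analysing
n ≈ 24 cohorts should expect this small anticonservatism, which is shared
with the procedure the pipeline reproduces. The sign-flip permutation test
is exact at any n and is calibrated at n = 24.

The power calculation uses the exact noncentral-t distribution (no normal
approximation — the approximation flips the answer at the 23/24 boundary):
the smallest n with one-sample, one-tailed power ≥ 0.90 at α = 0.05 for
d = 0.62 is n = 24, the cohort size the pipeline treats as standard.

## Model adjudication

The three accounts predict, for each of the eight cells (EVC/IPS ×
content/context × PMI/UMI), a significantly positive, null, or
significantly negative TR-10 slope. `model_predictions()` transcribes the
three 8-cell tables; `adjudicate_models()` classifies each observed cell at
the chosen α (after correction) and counts matches per model. The package
treats regions as *labels with configurable generative regimes*, so each
predicted pattern can be instantiated synthetically and recovered — an
integration test of the whole chain rather than a claim about brains.

## Synthetic BOLD generator

Each voxel receives a preferred location and orientation (uniform on the
feature spaces); its weight rows are the basis activations of those
preferences plus optional Gaussian weight noise. Per trial and TR the
signal is

amp_loc,PMI(t)·W_loc c(PMI loc) + amp_loc,UMI(t)·W_loc c(UMI loc) +
(same for orientation) + load(t) + baseline + noise,

with white Gaussian noise, a constant baseline intensity (100 by default,
so percent signal change against the run mean is well defined), and
additive ROI-wide load effects on load-of-2 trials. At configured
"remapping" TRs the UMI's channel vector is reflected about its mean
(c ↦ 2·mean(c) − c), the generative counterpart of a negative
reconstruction slope; the reflection is an involution and preserves the
channel mean. The default amplitude profiles rise over the first three TRs
and separate after the first cue's haemodynamic latency (UMI attenuated to
0.5 from TR 8); they are illustrative epoch gains standing in for
HRF-convolved regressors, not fitted time courses — the true amplitude
dynamics of real data are unknown. Time is trial-locked (12 TRs of 2 s);
there is no HRF convolution within the trial, no spatial structure, and no
temporal autocorrelation. Voxel tuning matches the analysis basis by
construction: the generator tests estimator correctness, not robustness to
tuning mismatch.

Cohorts share one trial schedule; subject-specific load gains g_s ~
Normal(1, 0.25) scale the load profiles, and the behavioural RT load effect
is ρ·standardize(g_s) + √(1−ρ²)·noise per dimension, scaled to 100 ms —
so the brain–behaviour correlation analysis has a known target ρ.

What passing tests therefore show: the estimators recover exactly what the
linear generative model encodes, the inference procedures hold their
levels, and injected priority/load/coupling regimes are detected where and
only where injected. What they do not show: robustness to voxel tuning
mismatch, realistic fMRI noise spectra, motion or physiological artifacts,
or spatial smoothing effects — all deliberately outside the generator.

## Numerical choices and degeneracies

- **Noise-free standardized data are degenerate by construction.** Channel
  activations sum to a near-constant across trials, so per-run z-scoring of
  noiseless data removes the constant direction of channel space and leaves
  the training data rank k−1; the inversion step then correctly refuses a
  singular ŴᵀŴ. Exact-recovery oracles therefore run on raw (un-z-scored),
  jitter-free data, where recovery is exact to 1e−6 and better; any
  realistic noise restores full rank under z-scoring.
- **Remapping sign recovery is exact at the channel level, near-exact after
  cross-decoding.** Reflecting a channel vector flips its slope exactly.
  The pipeline-level quantity, however, is estimated with PMI-trained
  weights, and with two simultaneously encoded items the uncued item leaks
  into the weight estimate; with equal amplitudes and zero noise the UMI
  slope equals −(PMI slope) to about 0.3% (asserted at 1% relative
  tolerance), with the sign recovered exactly.
- **Load-contrast localization is checked noise-free**, where non-injected
  TRs carry an exactly zero contrast (permutation p = 1) and the check is
  deterministic; under noise a null TR's p value is uniform, so "nothing
  elsewhere" is not a testable property of a stochastic run. Stimulus
  amplitudes are held at zero in these checks because with tuned signal
  present the ROI-mean response covaries slightly with inter-item distance
  in small voxel samples — a finite-sample confound between feature
  geometry and load that the pure-load oracle must exclude.
- **PSC denominator.** Z-scored runs make "percent" ill-defined, so percent
  signal change uses the run-mean raw intensity as denominator (recorded in
  the output schema); real-data users can substitute a raw baseline. A
  degenerate denominator (|run mean| below 1e−6) is an error naming the
  run.
- **Canonical HRF.** The GLM voxel-selection step uses a double-gamma HRF
  (gamma shapes 6 and 16, rate 1, undershoot ratio 1/6, normalized to peak
  1 near 5 s) convolved on a 0.1-s grid and sampled at the observed TRs of
  each run's trials; seven epoch regressors (sample, delay 1.1 boxcar,
  cue 1, delay 1.2 boxcar, probe 1, delay 2, probe 2) plus per-run
  intercept and linear/quadratic drift nuisances. Spatial smoothing is a
  no-op in the absence of voxel geometry and is documented as such.
- **Ties and bounds.** All-zero bootstrap or permutation difference
  distributions report p = 1; a one-sided-empty bootstrap reports the bound
  2/B with a flag; the multi-level distance ANOVAs are reduced to the
  binary load-of-1 vs load-of-2 contrast, mirroring the primary
  exploratory inference.

## Problem sizes used by the test suite

The suite validates at desk scale, chosen so the full run stays within a
few minutes: single-repetition designs (108 trials, 9 runs) for most unit
tests; the full 324-trial, 27-run design wherever an exact design
constant is asserted; 10–32 voxels per synthetic region; 100 random
instances for the closed-form/QR equivalence; 200 permuted-label
replicates; 100 replicate cohorts of 24 subjects (1,000 bootstrap
iterations) for remapping detection power, with noise calibrated once so
the per-subject UMI slope effect is d ≈ 0.62 — the smallest effect the
design was powered for; 500 replicate datasets for type-I calibration; and
20 replicate cohorts per coupling level for the brain–behaviour checks.
Iteration counts are reduced from the 10,000 defaults in tests only; the
package defaults remain the study-scale values (500 voxels per region,
24 subjects, 10,000 resamples).

## Known limitations

Real-data ingestion is limited to the events-TSV + numeric-array path; no
BIDS or NIfTI geometry handling. The generator's additivity of location
and orientation signals within a voxel is an assumption of convenience —
nothing is claimed about within-voxel feature interactions. Ridge or
Bayesian IEM variants, basis-phase iteration, and eye-tracking schedules
are out of scope.
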