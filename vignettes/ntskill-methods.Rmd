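---
title: "Assessing non-technical surgical skill from sensor time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing non-technical surgical skill from sensor time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntskill)
```

## The problem

Non-technical surgical skills — situation awareness, decision-making, and
resilience to stress and distraction — influence patient outcomes alongside
technical dexterity, but they are usually assessed with self-rating
questionnaires or expert panels, both labor-intensive and prone to bias.
`ntskill` implements an autonomous alternative for minimally invasive surgery
(MIS) box training: the trainee's workload is self-rated on the six-dimension
SURG-TLX instrument (mental demands, physical demands, temporal demands, task
complexity, situational stress, distractions; each 0–20), and those ratings
are used only as *class labels* for a classifier that sees nothing but
objectively measured sensor data — 2-D instrument trajectories tracked in the
video and a 3-axis force signal from the instrumented phantom. If the
classifier can recover a workload dimension from the sensors alone, that
dimension is autonomously measurable.

The modeled study design is a phantom laparoscopic-cholecystectomy task:
7 subjects (4 medical professionals, "MP"; 3 non-medical controls, "CG")
perform the task up to three times, 20 trials in total (one expert performed
only twice). Each trial yields a SURG-TLX response, a success/failure outcome
for the dissection step, frames from a fixed 2-D camera, and the resultant
force on the phantom along three axes.

## The synthetic cohort generator

No recorded data are distributed with this design, so every downstream stage
is exercised on synthetic cohorts whose statistical structure matches the
study conditions (`generator_config()`):

* **Cohort structure.** 7 subjects, trials `3,3,3,2,3,3,3` (subjects 1–4 MP,
  5–7 CG), giving 11 MP and 9 CG trials.
* **SURG-TLX scores** are drawn Normal(mean, sd) per dimension with the
  published group-level means/SDs (`surgtlx_group_params()`), rounded and
  clipped to 0–20. The instrument's endpoints are integers, so integer scores
  are assumed; rounding biases extreme means slightly toward the interior,
  which the sampling test tolerates explicitly.
* **Trajectories** are natural cubic splines through random waypoints in the
  inner 70 % of a 640 × 480 image (0-based pixels, origin top-left, x right,
  y down) plus white tremor noise; the clipper track is invalid before a
  randomly placed bleeding-onset frame (50–80 % of the trial), matching the
  workflow in which the clipper only enters after the induced bleeding.
* **Forces** are white Gaussian baseline noise (SD 1 in arbitrary units — no
  newton calibration is assumed) plus, on class-conditionally affected axes,
  a Poisson train (0.2 bursts/s) of half-sine bursts of 0.5 s whose amplitude
  is the configured effect in baseline-SD units.
* **Class-conditional effects.** Because the classifier's labels are defined
  relative to the cohort mean, the generator draws all responses first,
  binarizes them within the cohort, and then synthesizes signals conditioned
  on those labels. Defaults place a 3-SD burst effect on force-z for trials
  with high temporal demands and a 2-SD effect on force-x for high mental
  demands and situational stress, mirroring the associations the analysis is
  designed to recover — a strong temporal/force-z link and a weaker
  experience-aligned force-x link.
* **Outcome** is Bernoulli(0.35) independent of group (7 of 20 successes
  expected), configurable.
* Trial lengths default to 2 000–10 000 frames at 30 Hz — desk scale. Study
  scale (up to 94 068 frames) is reachable through the configuration. The
  force rate (100 Hz) deliberately differs from the frame rate so that
  synchronization is always exercised; neither rate is prescribed by the
  study description, so both are configurable.

What the generator does **not** emulate: real endoscopic video (specular
highlights, occlusions, deformation), physiologic force dynamics, respondent
psychology beyond group-level Gaussians, or any correlation structure between
dimensions beyond what the group means induce. Passing tests therefore
demonstrate that the pipeline recovers the effects it is pointed at, not that
real training data contain such effects.

## Workload statistics

Group comparisons use the **pooled-variance Student t-test** (two-tailed,
`df = n1 + n2 - 2`), also available directly from summary statistics
(`t_test_from_summary()`), since published group tables print only means and
SDs. Pooled rather than Welch was a deliberate choice: with the published
summaries (n = 11/9), Welch's test calls the distractions dimension
significant (p ≈ 0.042) while the pooled test reproduces the published
"not significant" call (p ≈ 0.052); the pooled test reproduces all six
published significance annotations. Learning curves use paired t-tests
between trial indexes 1–2, 2–3 and 1–3, dropping subjects that lack a trial
(the two-trial subject leaves 6 pairs for comparisons involving trial 3).

Significance annotation follows the published caption literally: `**` for
p < 0.0001, `*` for 0.01 < p < 0.05, nothing otherwise — the band
0.0001 ≤ p ≤ 0.01 is deliberately left unlabelled.

Binary labels for classification: scores strictly above the all-trial mean of
a dimension are class 1, ties and below are class 0 ("above average" read
strictly); experience maps MP→0, CG→1 so class 1 aligns with the
high-workload class; outcome maps success→1. With the published group
separation, mental-demand and situational-stress labels coincide with group
membership in nearly every cohort, which is why the results grid carries a
single combined experience/mental/stress row.

```{r stats-example}
group_workload_stats(summary = surgtlx_group_params())[, c("dimension", "t", "p", "annotation")]
```

## Instrument tracking

The tracker is a discriminative correlation filter with channel-reliability
weighting — a simplified relative of the CSRT family. The full CSRT's
segmentation-based spatial reliability map is replaced by a box-shaped
support (the windowed template), which is sufficient for compact targets; the
tracker sits behind a small interface (`init_tracker()`, `track_update()`,
`reselect()`, `track_sequence()`) so a heavier tracker can be substituted.

Details and defaults (all configurable in `tracker_config()`):

* Template = 2.5 × the manually supplied RoI; learned by frequency-domain
  ridge regression against a Gaussian target (σ = template width / 16,
  regularizer λ = 1e-3) on standardized, Hann-windowed feature channels
  (RGB input: intensity + two chroma channels; grayscale input: intensity +
  horizontal/vertical gradients).
* Per-frame update: channel-weighted correlation response over the search
  window; new center = response argmax with 3-point quadratic sub-pixel
  interpolation per axis (patch anchoring uses half-up rounding, which
  commutes with integer frame shifts — plain banker's rounding breaks exact
  shift equivariance). Filter and channel weights update with exponential
  rate η = 0.02; weights remain a probability vector.
* Confidence is the peak-to-sidelobe ratio (PSR, 11 × 11 peak exclusion),
  measured on the response of the *re-centered* patch: on the displaced
  response the Hann window attenuates a fast-moving target and healthy
  frames read like noise, whereas after re-centering genuine targets score
  well above the extreme-value baseline of a pure-noise response. Frames
  with PSR < 5 are flagged invalid, hold the last confident center,
  and do not update the filter. Manual RoI re-selection re-initializes the
  filter at any frame, as needed after large-scale motions.

## Series assembly

Each trial becomes a T × 9 matrix in fixed channel order: dissector x/y,
scissors x/y, clipper x/y, force x/y/z. Force samples are assigned to frames
by **nearest timestamp** (exact ties to the earlier sample, with a relative
1e-9 guard so binary floating point cannot flip a tie). Frames where a tool
is invalid or absent carry 0 in its channels — the same value as the
end-padding that brings every trial to the cohort's maximum length — so
"missing" and "padded" share one semantics (validity flags are preserved in
the on-disk track files for audit). An optional integer stride downsamples
after assembly and before padding for desk-scale classifier runs.

Channels are z-normalized per channel with statistics computed **over the
unpadded rows of training trials only**; padded rows stay exactly 0 (the
post-normalization mean). Without this, pixel coordinates (~10²) would
dominate force units in the gradients, and computing statistics per fold
prevents the held-out trial from leaking into its own scaling.

## The classifier

A fully convolutional network for multivariate time series: three blocks of
1-D convolution (64 filters each, kernel sizes 8, 5, 3, "same" temporal
padding), batch normalization (ε = 1e-5, running-statistic momentum 0.9),
and ReLU; global average pooling (GAP) over time; a 2-way softmax head. The
kernel sizes follow the standard configuration of this architecture family;
the filter counts are fixed by the design. Training hyperparameters are not
prescribed by the study description and default to Adam at 1e-3, batch size
4, 100 epochs (30 in the desk-scale evaluations); initialization and
minibatch order come from R's RNG, so training is deterministic given the
seed. A compiled (RcppArmadillo) training core and a plain-R reference loop
implement identical arithmetic and are pinned to each other in the tests.

GAP averages over the full padded length by default, as nothing in the study
description suggests masking; zero padding after per-fold normalization
dilutes the pooled features roughly in proportion to the padding fraction,
which the tests quantify (a 3-SD effect still classifies at 50 % padding).
`fcn_config(masked_gap = TRUE)` averages only over the unpadded rows for
ablation.

## Evaluation protocol

Leave-one-out cross-validation over the 20 trials: for each fold the
normalization statistics and the network are fit on the 19 remaining trials
and the held-out trial is predicted; accuracy is the mean 0/1 correctness
over folds. Two protocol decisions the study description leaves open:

* A fold whose 19-trial training set collapses to a single class (possible
  for heavily unbalanced labels such as outcome) predicts that class instead
  of erroring, so LOOCV always completes.
* Per-fold training seed = master seed + fold index; per-cell seeds in the
  full grid are offset the same way, so every cell and fold is independently
  reproducible.

`full_grid()` evaluates all six label dimensions against ten channel subsets
(forcex/y/z, forcexyz, Dxy, Sxy, Cxy and three combinations). At the
desk-scale defaults used throughout the tests and the acceptance script —
trials of 2 000–10 000 frames, stride 10 (T ≤ 1 000), 30 epochs, full
(64, 64, 64) filters — one LOOCV cell takes a few minutes on one CPU; the
all-cells null-grid check in the tests uses a reduced scale (T ≈ 120, (8, 8, 8)
filters, 10 epochs) because chance-level behaviour under a zero-effect cohort
does not depend on network capacity. The null check uses a simultaneous
acceptance band across the 60 dependent cells ([3/20, 17/20] per cell plus a
grand-mean check) rather than a per-cell 95 % band, which would be expected
to fail somewhere by chance even under a perfect null.

## Numerical and degenerate-input choices

* Pooled t-test with two zero SDs and equal means returns t = 0, p = 1; with
  unequal means it errors (no sampling variance to test against).
* `annotate()` rejects p outside [0, 1]; binarization of a constant dimension
  yields all-zero labels (tie rule).
* Tracker RoIs must be at least 8 × 8 px and intersect the frame; sub-pixel
  interpolation clamps to ±0.5 px and guards a zero second difference.
* Softmax is computed with max-subtraction; log-loss is floored at 1e-12.
* A zero-SD channel is centered but not scaled.
* An exact softmax tie predicts class 0.

## Limitations

The pipeline validates parameter recovery on synthetic data; accuracies
obtained here do not transfer to recorded training data, where effect sizes,
noise structure and label reliability are unknown. The tracker is a
simplified correlation filter — adequate for rendered discs and compact
high-contrast targets, not for deformable or occluded instruments in real
video. The t-tests assume independent trials within groups, as the group
comparison design does, although repeated trials by the same subject are
correlated. No multiple-testing correction is applied across the six
dimensions or the 60 grid cells, matching the reported analysis.
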