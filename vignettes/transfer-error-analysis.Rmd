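---
title: "Quantifying between-individual transfer error in fMRI pain decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying between-individual transfer error in fMRI pain decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painxfer)
```

## The problem

Multivariate decoding models that predict a person's subjective pain rating
from their trial-level evoked BOLD features work well within an individual
but degrade sharply when a model trained on one individual is applied to
another. `painxfer` implements an analysis that decomposes *why*: it
quantifies, for every ordered (training, test) pair of individuals, both the
prediction error and the individual differences in ratings and in features,
and then asks which differences, and at which voxels, explain the error.

## The decoding model

Each individual `j` contributes a trial-by-voxel feature matrix `B` and a
rating vector `R` (0–10 visual analog scale). The decoding model is linear,

    R_i = B_i a + a_0,

fitted by partial least squares regression with the SIMPLS algorithm:
orthonormal score vectors are extracted iteratively from the mean-centered
data so that each maximizes covariance with the centered response, the
response is regressed on the scores, and the weights are folded back into a
coefficient vector `a` on the original feature scale. Centering both blocks
implies the *centering identity*: the mean fitted value on the training
trials equals the mean training rating, so resubstitution bias is exactly
zero. At full rank SIMPLS coincides with ordinary least squares, which the
test suite uses as an independent oracle.

The number of latent components is the smallest count whose cumulative
coefficient of determination (fitted response variance over total response
variance) reaches a threshold, 0.95 by default, capped at 10 components.
Both knobs are exposed in `pipeline_config()`; the threshold criterion is
part of the method, while the particular values are conventional choices
since nothing stronger is known.

## Error metrics and the transfer scheme

`pairwise_predict()` applies every model to every individual: `n^2` ordered
pairs (900 for 30 individuals), of which the `n(n−1)` off-diagonal cells
are between-individual transfers and the diagonal is within-individual
prediction. Each pair is summarized by

* **MAE** — mean |predicted − actual|, unsigned overall error;
* **MPB** — mean (predicted − actual), signed bias; `|MPB| ≤ MAE` always.

Within-individual prediction defaults to resubstitution, the literal
reading of the scheme; because of the centering identity this forces the
diagonal MPB to zero, so a k-fold mode (`within_mode = "kfold"`) is provided
when an honest within-individual error is wanted. Predictions are never
clipped to the rating scale: clipping would bias MPB toward zero.

## Individual-difference metrics

For each ordered pair (training `s`, test `t`):

* **DIST_PAIN** / **DIST_BOLD** — the Bhattacharyya distance between the
  two individuals' rating distributions / per-voxel feature distributions.
  The distance of two distributions is `−log ∫ sqrt(p q)`; for finite
  samples of a continuous variable an estimator must be chosen, and the
  default plugs sample means and unbiased variances into the Gaussian
  closed form
  `D = (μ1−μ2)²/(4(σ1²+σ2²)) + log((σ1²+σ2²)/(2σ1σ2))/2`,
  with a variance floor of 1e−9 against degenerate samples. A
  histogram estimator on shared breaks (`estimator = "histogram"`) is
  shipped for sensitivity analysis; on 40-trial samples it is noticeably
  coarser, which is why the smooth Gaussian form is the default.
* **DIFF_PAIN** / **DIFF_BOLD** — the signed test-minus-training difference
  of mean ratings / per-voxel mean features.

Distances are symmetric and zero only for matching moments; differences are
antisymmetric. Pairs are enumerated training-major with an explicit
`pair_index` table so every per-pair artifact is joinable across stages.

## Correlation maps and inference

Across the between-individual pairs, unsigned metrics are correlated with
MAE and signed metrics with MPB (Pearson), scalar for ratings and voxel-wise
for features. Two inference modes exist for the voxel-wise maps:

* **parametric** (default): per-voxel t-based p-values with Bonferroni
  family-wise correction over in-mask voxels. This treats the 870 pairs as
  independent, which they are not — each individual appears in 58 ordered
  pairs, so the effective sample size is closer to the number of
  individuals than to the number of pairs, and the p-values are
  anti-conservative. The mode is retained as the default because it is what
  the analysis it reimplements does, and because the *signs and relative
  magnitudes* of the correlations, not their p-values, carry the scientific
  conclusions.
* **permutation** (`inference = "permutation"`): a max-statistic permutation
  test that relabels the *individuals* underlying the metric's pair
  structure and uses the permutation distribution of the maximum |r| over
  voxels. Under exchangeability of individuals this yields exact
  family-wise error control; it is the mode whose calibration the test
  suite verifies on null cohorts. It is the right choice whenever the maps
  are to be thresholded for inference rather than description.

The group-level predictive map (`group_predictive_map()`) is a per-voxel
one-sample t-test of the model coefficients across individuals with
Bonferroni correction; here the individuals genuinely are the sampling
units, so the parametric correction is valid (and conservative).
Zero-variance voxels are excluded from significance rather than crashing.

## What the synthetic cohorts emulate

No raw data accompany the design, so `generate_cohort()` simulates cohorts
whose structure matches the assumptions the analysis rests on, with ground
truth recorded. Defaults mirror the study design: 30 individuals, 10 trials
at each of 4 laser energies in random order, ratings on a 0–10 scale, and a
12×12×12 grid carrying four planted 27-voxel regions — two positively
predictive (S1-like, insula-like), one negatively predictive (mPFC-like),
and one sign-heterogeneous modulator (precuneus-like) whose weights are real
within each individual but carry a random sign per individual, so their
across-individual mean is zero. All other voxels are null.

Ratings follow `R = clip(α_j + β_j d + ε, 0, 10)` with drive `d` linear in
energy-level index — the simplest monotone psychophysical choice — an
individual offset `α_j ~ N(1, 1.2)`, an individual range `β_j ~ N(8, 1.5)`
(the design reports usable rating ranges around 8), and trial noise of SD 1.
Individuals whose realized range falls below 4 are redrawn, mirroring the
design's exclusion of participants without usable rating variation.

Features realize a *stimulus-driven* evoked response: region voxels carry a
per-individual amplitude `A` (1.5% fractional signal change per unit drive
on average, across-individual coefficient of variation 1.0, per-voxel
jitter 10%, per-region relative scales 1, 1, 1.4, 0.9), and
`B = polarity·A·d + δ0 + η` with independent per-individual voxel offsets
`δ0 ~ N(0, 0.003)` and trial noise `η ~ N(0, 0.015)`. Algebraically this is
exactly the rating-coupled form `B = w·R + δ + η` with `w = polarity·A/β`
and `δ = −w·α + δ0`. The distinction matters: the report offset `α` does
*not* propagate into the features. This is the standard account in which
BOLD tracks the nociceptive input while idiosyncratic scale use adds a
report offset, and it is what produces the empirically observed error
structure — transfer bias dominated by rating offsets (strongly negative
DIFF_PAIN↔MPB coupling), while amplitude heterogeneity couples DIFF_BOLD to
MPB *positively* at positively predictive voxels and negatively at the
negatively predictive region. A generator in which `α` leaks into the
features through `w·R` cannot reproduce both signs at once, which we
verified analytically and by simulation before fixing this design.

The free effect sizes (amplitude CV, noise levels, offset SDs) were chosen
once so that the simulated cohorts land in the reported descriptive regime
of this kind of experiment — between-individual MAE near 2.6 with SD near
1, |DIFF_PAIN| near 1.5, DIST_PAIN near 0.1, a strong negative
DIFF_PAIN↔MPB correlation, a moderate positive DIST_PAIN↔MAE correlation,
and voxel-level BOLD–error correlations substantially weaker than the
rating-level ones — and were not revisited afterwards.

What the generator does **not** emulate: hemodynamic convolution and
serial structure (trials are exchangeable; the timecourse module only wraps
features in a canonical-shaped series peaking at the 4th post-onset scan),
spatial autocorrelation beyond the planted regions, head motion and
physiological noise, and inter-stimulus timing. Passing tests therefore
show that the *analysis* behaves as designed under its own assumptions, not
that real fMRI data satisfy those assumptions. The optional
`adaptation_slope` knob adds a per-trial rating drift (habituation);
whether evoked features adapt similarly is an open question in the
literature, so the knob deliberately affects ratings only and no analysis
stage consumes it.

## Feature extraction conventions

Trial series are normalized by subtracting and then dividing the baseline
value at stimulus onset, so a gain applied to the raw series cancels. The
decoding feature is the normalized value at **exactly the 4th scan after
onset** — the scan at which the evoked response peaks at a 1.5 s TR — not a
running maximum, which would be noise-biased. The onset scan is the
reference index; "4th scan after onset" means `onset_index + 4`. Zero
baselines raise an error naming the trial and voxel.

## Numerical choices and degenerate inputs

* SIMPLS rank exhaustion is detected from the collapse of the score norm
  (relative tolerance 1e−10 against the first component); `fit_simpls()`
  errors, while `select_n_components()` truncates and warns.
* Constant ratings are a degenerate response and error out.
* Zero-variance voxels are excluded (group map: p forced to 0/1 by the sign
  convention; correlation maps: column dropped) and logged via messages.
* The Bhattacharyya variance floor is 1e−9; the histogram estimator floors
  the coefficient at 1e−12 to avoid infinite distances for disjoint
  supports.
* All randomness flows through `derive_seed()` from one top-level seed:
  cohorts, trial noise, and permutation draws are reproducible, and
  `run_pipeline()` output is identical for identical configs.

## Problem sizes used in the test suite

The Monte-Carlo suites keep the study-sized 30-individual, 40-trial design
but run on reduced grids (8³ with the same four 27-voxel regions; 6³ for
null-calibration cohorts, which have no regions), with 100 cohorts for the
sign-recovery suite, 50 for the modulator-dissociation suite, and 200 for
the family-wise error calibration. These sizes keep each suite at a few
minutes while leaving the per-cohort statistics at full design strength.

## Known limitations

* The parametric voxel-wise p-values inherit the pair non-independence
  problem described above; use the permutation mode for thresholded claims.
* The Gaussian Bhattacharyya estimator is exact only under normality of the
  trial distributions; ratings clipped at the scale ends violate this
  mildly.
* Within-individual resubstitution understates honest within-individual
  error; use the k-fold mode for that comparison.
* The generator's null voxels are white-noise; family-wise error control
  verified there does not speak to spatially correlated noise.
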