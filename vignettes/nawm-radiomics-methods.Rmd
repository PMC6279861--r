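---
title: "Longitudinal NAWM radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal NAWM radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

White matter hyperintensities (WMH) are bright FLAIR lesions of the aging
brain. The tissue around them — normal-appearing white matter (NAWM) — looks
normal on conventional images but may already be microstructurally damaged.
In a longitudinal design with a baseline and a follow-up scan, NAWM splits
into tissue that converts to visible WMH during the interval (*developing*
NAWM, dNAWM) and tissue that does not (*non-dNAWM*); control subjects
contribute normal white matter (NWM). The question is whether quantitative
texture analysis of the **baseline** image can discriminate these classes —
that is, whether conversion is predictable before it is visible.

`nawmrad` implements the full analysis as a reusable, testable pipeline:

1. **ROI construction** (`subtract_masks()`, `mirror_mask()`): the dNAWM
   region is the set difference follow-up WMH minus baseline WMH on
   co-registered images; the non-dNAWM reference is placed mirror-symmetric
   about the brain midline. All analysis ROIs must have at least 100 pixels
   (`validate_roi()`).
2. **Texture battery** (`extract_battery()`): first-order histogram
   statistics, shape (form-factor) descriptors, Haralick gray-level
   co-occurrence (GLCM) features and Galloway run-length (RLM) features at
   angles 0/45/90/135 degrees and offsets 1, 4, 7, with `AllDirection`
   (mean over angles) and `AllDirection_SD` (population SD) aggregates —
   396 named features by default.
3. **Selection cascade** (`run_cascade()`): ANOVA + Mann–Whitney univariate
   filter, Spearman redundancy pruning, LASSO-penalized logistic selection —
   run on training rows only.
4. **Models** (`fit_logistic()`): unpenalized multivariable logistic
   regression for the three contrasts Model 1 (NWM vs dNAWM), Model 2
   (non-dNAWM vs dNAWM), Model 3 (NWM vs non-dNAWM).
5. **Evaluation** (`roc_auc()`, `hosmer_lemeshow()`, `icc_agreement()`):
   ROC/AUC with DeLong or bootstrap confidence intervals and a Youden
   operating point, deciles-of-risk calibration, and ICC(2,1) agreement.

Because no patient images are distributed, the package ships a seeded
synthetic-cohort generator whose statistical structure matches the study
design, so every downstream stage is exercised end to end.

## The texture battery

Gray levels are quantized per ROI into `ng = 16` equal-width bins over the
ROI's own min–max range (the extractor settings of the original commercial
software are unpublished; `ng` is configurable). GLCMs are **mask-aware**
(both pixels of a pair must lie inside the ROI), symmetrized by adding the
transpose, and normalized to unit sum. Entropies use base-2 logarithms with
the `0 log 0 = 0` convention; the base is configurable and affects scale,
not selection behaviour.

The RLM "offset" deserves a note: run-length matrices are classically
defined for adjacent pixels only, yet the feature naming convention pairs
run-length features with offsets 1, 4, 7. `compute_rlm()` interprets the
offset as a **traversal stride**: each line in the run direction is split
into its `d` interleaved subsequences, runs are counted within
subsequences, and the stride-`d` subsequences partition the mask so every
pixel is covered exactly once per direction (`offset = 1` is the classical
Galloway construction). This keeps the coverage identity
`sum(l * r(i, l)) =` pixels traversed exact for every direction and stride,
which the test suite asserts on random masked patches. The semantics of the
original extractor cannot be verified; the stride reading is a documented
assumption.

Whether "Uniformity" denotes histogram energy or a GLCM quantity is
ambiguous in the field; it is treated here as the low-order histogram
energy `sum(p_i^2)`, which is the reading consistent with describing it as
a low-order feature.

## The synthetic cohort generator

Each texture class is a stationary random field: spectrally filtered
Gaussian white noise with a Gaussian transfer function, giving two
interpretable knobs — the marginal SD `noise_sd` and the autocorrelation
scale `correlation_length` (pixels). A third knob, `dispersion` in [0, 1],
blends the standardized field pixel-wise with its probability-integral
transform, interpolating the marginal distribution from Gaussian to
uniform while preserving spatial coherence.

`dispersion` exists because of a subtlety worth recording: the battery
quantizes each ROI over its own min–max range, so histogram and
co-occurrence statistics of a *Gaussian* field are invariant to rescaling
`noise_sd` — heterogeneity expressed purely as marginal variance is
invisible to Uniformity and IDM. What those features actually measure under
ROI-relative quantization is the *shape* of the marginal (how evenly
intensities fill their range) and the bin-to-bin co-occurrence structure.
An early design that modelled heterogeneity as sparse hyperintense
micro-foci moved both features the wrong way (a few bright pixels stretch
the range and concentrate the bulk into fewer bins). The dispersion
transform moves both features monotonically in the intended direction, as
the test suite verifies.

Default class parameters (frozen; `default_class_params()`):

| class     | mean | noise_sd | correlation_length | dispersion |
|-----------|------|----------|--------------------|------------|
| NWM       | 480  | 30       | 2.2                | 0.00       |
| non-dNAWM | 484  | 34       | 2.5                | 0.25       |
| dNAWM     | 490  | 55       | 3.0                | 0.75       |

Intensities are arbitrary units in [0, 1000]; the follow-up WMH region is
raised by `lesion_intensity_boost = 220`. The ordering NWM < non-dNAWM <
dNAWM in heterogeneity reproduces the qualitative boxplot ordering of
Uniformity and IDM and the qualitative AUC ordering of the three models;
the published AUC magnitudes themselves depend on the unavailable patient
images and are deliberately not calibration targets.

Between-subject variability matters: a single ROI of 250–400 pixels
estimates its texture parameters precisely enough that fixed class
parameters would make even nearby classes almost perfectly separable. Each
subject therefore draws a random effect shared across its tissue classes
(log-SD 0.10 on `noise_sd`, 0.08 on `correlation_length`, additive 0.06 on
`dispersion`, additive SD 15 on the mean), so class overlap — and hence
model AUC — is governed by biological-style between-subject spread.

Geometry: lesions are periventricular-like ellipses; the follow-up ellipse
strictly contains the baseline one (same center, larger radii), so the
dNAWM annulus is the exact set difference and mask containment holds by
construction. The non-dNAWM region is the annulus mirrored about the
vertical midline. Images default to 96 x 96 pixels, a crop around the
periventricular region; the generator retries geometry draws until the
annulus reaches `roi_min_pixels` (default 100) and raises a diagnostic
generation failure if it cannot.

What the generator does **not** emulate: anatomy, scanner noise spectra,
bias fields, registration error, partial-volume effects. Passing tests
therefore demonstrate that the pipeline's statistics behave correctly under
the assumed data-generating model, not that the biological effect sizes of
real FLAIR are reproduced.

## Statistical design choices

- **Univariate filter.** A feature must pass *both* the two-group ANOVA
  (pooled-variance F test, equivalent to the t-test) and the two-sided
  Mann–Whitney U (tie-corrected normal approximation) at `alpha = 0.05` —
  the conservative reading of "ANOVA+MW"; a union mode is available. No
  multiple-testing correction by default (single stated criterion
  p <= 0.05); Benjamini–Hochberg available via `adjust`.
- **Redundancy pruning.** Pairs with |Spearman rho| > 0.9 are resolved by
  dropping the member with the larger mean absolute correlation against the
  remaining features; ties break by larger univariate p, then reverse
  lexicographic name — fully deterministic. The threshold is unstated in
  the motivating study and is configurable.
- **LASSO.** Stratified 10-fold cross-validated binomial deviance, penalty
  at the minimum-deviance lambda (`"1se"` available); features standardized
  on training data. If no coefficient survives, the model falls back to the
  stage-2 survivors, flagged in the result.
- **Split.** 7:3 stratified by class with per-class half-up rounding:
  0.7 x 102 = 71.4, but per-class round(0.7 x 51) = 36 gives the published
  72/30 design exactly. The pipeline splits at the *subject* level so the
  two ROIs of a case subject never straddle the train/test boundary, and
  one split is shared by the three contrasts.
- **Refit.** The final models are unpenalized maximum-likelihood logistic
  fits on the selected features (selection/estimation split). Complete
  separation — common when the training classes are cleanly separable — is
  detected and flagged; coefficients are then unstable even though ranking
  (AUC) remains usable.
- **ROC.** AUC by trapezoid (equal to the normalized Mann–Whitney statistic
  with half-tie credit); 95% CI by DeLong (default) or stratified
  bootstrap; the operating point maximizes the Youden index, ties resolved
  toward the lower threshold.
- **Calibration.** Hosmer–Lemeshow with 10 deciles of risk; groups with
  degenerate expected counts merge with a neighbor; p from chi-square with
  `groups - 2` degrees of freedom (the reference distribution for
  model-fitted probabilities — the calibration simulations in the test
  suite fit the model before testing, which is the regime where the
  statistic is chi-square distributed).
- **ICC.** Two-way random effects, absolute agreement, single measures —
  ICC(2,1) — with the McGraw–Wong F-based confidence interval; the
  conventional choice for inter-/intra-reader agreement of repeated feature
  measurements.
- **Mann–Whitney U convention.** `mann_whitney_u()` reports
  `min(U_x, U_y)` (0 under complete dominance) and both one-sided
  statistics, because published tables differ in convention.

## Numerical and degenerate-input conventions

Coordinates are 0-based (row, column), row-major, everywhere a patch
exposes them. Constant patches quantize to bin 1 (Uniformity 1, entropy
0). A GLCM with no valid pair and an RLM with no run raise typed
degenerate conditions; inside `extract_battery()` these become flagged
`NA` features (never silent zeros) and such features are excluded before
the selection cascade. Correlation of a one-bin GLCM is reported as 0 with
a degenerate flag. Logistic fits converge to 1e-10 or error.

## Problem sizes used by the automated checks

The test suite runs the full design (51 + 51 subjects, 153 ROIs) for the
effect-direction and discrimination checks over ten seeds, and smaller
12 + 12-subject cohorts at 64 x 64 pixels for null-calibration sweeps;
texture-engine oracle checks use at least a hundred random patches up to
12 x 12 pixels with up to 8 gray levels, compared against brute-force
references at 1e-10 relative tolerance. These sizes were chosen so the
whole suite runs in a few minutes on one CPU while keeping every check at
the design's native 51/51 scale where the design itself is the point.

## Known limitations

- The default battery has 396 features; the commercial extractor's
  composition (printed count 384) is unpublished and not reproduced
  feature-for-feature.
- 2D, single-slice analysis only; no wavelet/filtered-image features.
- The synthetic generator's effect sizes are a modelling choice; published
  coefficient values and AUC magnitudes are not reproduction targets.
- Real-scan co-registration is out of scope: the pipeline requires
  pre-registered inputs and treats registration as a solved upstream step.
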