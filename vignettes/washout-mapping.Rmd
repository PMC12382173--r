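---
title: "Rapid wash-out and late-enhancement mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid wash-out and late-enhancement mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(washmap)
```

## The method

Glioblastoma tissue takes up and clears gadolinium quickly, with peak
T1 enhancement roughly 3–8 minutes after injection; metastases and
other slowly filling tissues peak much later (around 15 minutes or
beyond). Acquiring two post-contrast 3D T1-weighted volumes — an early
one at about 5 minutes and a late one at about 25 minutes — therefore
separates the two behaviors: tissue whose signal *falls* between the
two acquisitions is washing contrast out, tissue whose signal *rises*
is still accumulating it (late enhancement, "wash-in").

`washmap` implements this as a four-stage pipeline:

1. **Rigid co-registration** (`register_rigid()`): the late volume is
   aligned to the early one with a 6-degree-of-freedom rigid transform
   (same subject, same session; nothing nonrigid should have changed).
   The similarity metric is maximized by Nelder–Mead over a
   multi-resolution pyramid (default downsampling factors 4, 2, 1, two
   warm-started optimizer runs per level). Normalized cross-correlation
   is the default metric — the two acquisitions come from the same
   scanner and sequence, so their intensities are linearly related —
   with mutual information available for cross-field-strength pairs.
   The early scan is always the fixed image: the wash-out map lives on
   the early grid, and choosing the earlier acquisition as the
   reference keeps lesion geometry closest to any subsequent
   preoperative imaging.
2. **Intensity normalization** (`normalize_pair()`): a gain + offset
   map is fitted from the registered late volume to the early volume
   over *normal-appearing brain*: the brain mask minus the top 2% of
   early intensities and minus any supplied lesion mask, so true
   enhancement change cannot be fitted away. The gain is estimated by
   orthogonal (total least-squares) regression. This choice matters:
   both acquisitions carry comparable noise, and ordinary regression of
   one on the other attenuates the gain toward zero when the reference
   tissue is nearly homogeneous (a classical errors-in-variables
   effect we observed directly on phantoms). The offset then matches
   the medians, making the median paired difference over the reference
   set exactly zero; normalization is idempotent by construction.
3. **Map computation** (`compute_map()`): the signed wash-out
   percentage is `100 * (early - late) / early` wherever the early
   signal is positive, 0 elsewhere. Positive values are wash-out,
   negative values late enhancement. The percent scale is relative to
   the early acquisition — the denominator is a declared convention of
   this package; a difference-only map can be had by treating the
   percent map as `early - late` times `100/early`. Voxels are labeled
   WASHOUT / LATE_ENHANCEMENT / NEUTRAL with a dead-band `epsilon`
   (default 5%) that absorbs residual noise and normalization error.
4. **Volumetry** (`trace_lesion()`, `compartment_volumes()`,
   `washout_ratio()`): lesions are traced slice-by-slice as 2D
   connected components within an intensity band (a level-trace
   analog), compartment volumes are voxel counts times voxel volume,
   and the wash-out ratio is

   `washout ratio = V(wash-out) / (V(wash-out) + V(late enhancement))`.

   The rCBV ratio is the mean of three single-slice tumor ROI means
   divided by a contralateral normal-brain ROI mean; the ADC ratio is
   the solid-tumor ROI mean over the contralateral hemisphere mean.

The statistical layer (`welch_t()`, `roc_analysis()`, `icc2k()`,
`fit_linear_model()`, `cohort_report()`) evaluates how these ratios
separate glioblastoma from metastasis: Welch t-tests (computable from
published mean/SD/n summaries as well as raw data), tie-aware empirical
ROC AUC with Youden's J threshold and DeLong confidence intervals,
ICC(2,k) interrater reliability with Koo–Li bands, and the linear
probability model `tumor type ~ wash-out ratio + rCBV ratio + ADC ratio
+ volume`.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `epsilon` (dead-band) | 5 | percent | residual noise in the percent map is ~2% per 2% image noise; 5% leaves headroom without eating into true compartment contrast (tens of percent) |
| registration metric | NCC | — | same-scanner monotone intensity relation; MI for cross-field-strength pairs |
| pyramid levels | 4, 2, 1 | — | 10 mm / 10° capture range at the coarse level, sub-voxel refinement at full resolution |
| normalization trim | top 2% | — | excludes strongly enhancing voxels from the reference set |
| minimum lesion size | 3 × 3 × 3 | mm | excludes micrometastases whose wash-out ratio is unmeasurable; interpreted as the per-axis bounding-box extent, boundary-inclusive |
| small-tumor threshold | 1000 | mm³ | sensitivity analysis excluding lesions under 1 cm³ |

Two conventions deserve emphasis because the underlying clinical
protocol leaves them open: the percent denominator (early signal, see
above) and the interpretation of the 3 mm rule (minimum bounding-box
extent per axis, inclusive — a lesion of exactly 3 mm is retained).
Enhancing tumor volume is measured on the early acquisition by default.

## The phantom generator

`phantom_spec()` / `render_phantom()` produce a synthetic
dual-timepoint acquisition with complete ground truth:

* **Enhancement kinetics**: each lesion compartment follows a
  gamma-variate-style curve `E(t) = A (t/tp)^a exp(a(1 - t/tp))` —
  unimodal, zero at injection, peak `A` exactly at `tp`. The shape
  `a = tp * sqrt(rise * decay)` couples the rise and clearance rates.
  Archetypes: glioblastoma-like (peak 5 min), metastasis-like (peak
  15 min), slow-fill (peak 25 min). Signal units are arbitrary
  throughout — contrast dose and relaxivity are deliberately out of
  scope, so only the *relative* temporal behavior is modeled.
* **Geometry**: a left–right symmetric ellipsoid brain (baseline 100)
  with mirrored ventricles, a mild intensity gradient and a smooth
  deterministic sinusoidal texture standing in for internal anatomy.
  The texture is not decoration: a nearly homogeneous ellipsoid is
  rotationally ambiguous and would make rigid registration
  ill-posed in a way real brains are not. The grid is centered so the
  first-axis index flip is an exact world-space reflection, making
  contralateral (mirror) correspondence exact. The default lesion is
  two tangent spheres — a rapidly washing-out compartment and a slowly
  enhancing one, 60/40 by volume (`two_compartment_lesion()`). Compact
  compartments are used instead of concentric shells because a thin
  spherical shell is destroyed by the two unavoidable trilinear
  interpolations (scanner-side motion, then realignment) — a
  voxelization artifact, not a property of the mapping method.
* **Degradations**: rigid inter-scan motion applied to the late
  acquisition (forward warp, trilinear), a smooth multiplicative bias
  field (trilinear upsampling of a coarse random grid, scaled to a
  peak relative amplitude), and additive Gaussian noise (Rician
  optional) on both acquisitions. Truth masks come from the noiseless
  curves: an enhancing voxel is wash-out iff `E(t1) > E(t2)`.
* **Default problem size**: 96 × 96 × 72 voxels at 1.5 mm isotropic.
  Clinical 3D T1 images are commonly ~1 mm; 1.5 mm preserves every
  geometric property that matters here (compartments tens of voxels
  across) at a fraction of the cost, and the validation suite of 20
  degraded phantoms completes in a few minutes on one core.

What the phantom does *not* emulate: real anatomy, MR acquisition
physics (no T1 relaxometry or pulse sequences), DSC time-series (rCBV
and ADC maps are consumed as precomputed parameter maps with
configurable tumor-to-contralateral ratios), skull or scalp, and
nonrigid motion. Passing the phantom suite therefore demonstrates the
pipeline's numerical correctness — registration recovery, normalization
behavior, labeling and volumetric accuracy under controlled noise,
bias and motion — not robustness to anatomy-specific failure modes
(susceptibility distortion, pulsation artifacts, infiltrative margins).

The cohort simulator (`cohort_spec()` / `simulate_cohort()`) is the
second synthetic layer: it draws per-lesion wash-out, rCBV and ADC
ratios and tumor volumes from truncated normal distributions at the
published group means and SDs (29 glioblastoma lesions, 53 metastases;
wash-out ratio truncated to [0, 1] per its observed range, the other
measures to positive values), by rejection sampling under a single
seed. Its purpose is to reconstruct cohort-level discrimination
statistics (AUCs) from printed summary statistics when patient-level
data are unavailable; `truncnorm_mean()` / `truncnorm_auc()` provide
the closed-form and quadrature oracles the simulation is tested
against.

## Numerical choices and degenerate inputs

* Registration restarts Nelder–Mead once per level and lightly smooths
  (0.7 voxel Gaussian) at full resolution: trilinear interpolation
  imprints a shallow ripple on the metric surface that can trap the
  simplex a degree or so from the optimum.
* Non-convergence is flagged (final NCC below 0.5, or a metric that
  degrades across levels), never silently returned; disjoint fields of
  view are an error before any optimization.
* Normalization refuses reference sets under 1000 voxels.
* Wash-out ratio with both compartment volumes zero is *undefined* and
  reported as `NA` with a `ratio_undefined` flag — never coerced to a
  number.
* ROC threshold search uses midpoints between sorted unique scores;
  when several thresholds tie on Youden's J, the one with the highest
  specificity is reported (the tie-break is a documented convention).
  The positive class is metastasis, detected by *low* scores, encoded
  explicitly in the result's `direction` field.
* ICC(2,k) with zero error mean-square (perfect agreement) returns the
  point estimate with an undefined F-based interval rather than
  dividing by zero.
* `fit_linear_model()` reproduces the published analysis literally as
  an ordinary least-squares linear probability model on a 0/1-coded
  outcome; a logistic option exists but is not the reference path.
  Rank-deficient designs are an error naming the collinear columns.
* No multiple-testing correction is applied anywhere, matching the
  evaluated protocol (significance at p < 0.05).

## Design decisions that were genuinely open

* **Registration target**: the early acquisition is the fixed image
  (see above); the clinical protocol does not state the choice.
* **Two-rater averaging**: scalar measurements are averaged
  arithmetically per lesion (`average_raters()`); ICC is computed from
  the pre-average per-rater table.
* **Dice scoring of phantom recovery** is computed within the lesion
  region (the truth enhancing mask standing in for the rater's trace):
  per-lesion measurement is the unit of analysis, and outside the
  trace the map is never measured.
* **Table-level counting** is per lesion, not per patient (29
  glioblastoma manifestations vs 53 metastases).
* **ROI automation on phantoms**: the three rCBV slice ROIs are the
  lesion's three largest-area slices; the contralateral ROI is the
  midsagittal mirror of the lesion mask. On clinical data ROIs are
  user-supplied.

## Known limitations

* Rigid-only registration; severe inter-scan motion with nonrigid
  components (or gross susceptibility distortion) is out of scope.
* The brain mask is a simple intensity threshold; clinical data with
  skull or strong inhomogeneity should be masked upstream.
* The bias-field model is a single smooth multiplicative field; the
  global linear normalization absorbs its mean but not its spatial
  structure, which is why the dead-band exists.
* Cohort simulation treats measures as independent within group; the
  published combined-marker (rCBV × wash-out) AUC depends on their
  unknown correlation, so only its qualitative behavior is
  reproducible.
* The linear probability model can predict outside [0, 1]; it is kept
  because it replicates the published analysis, not because it is the
  best classifier.
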