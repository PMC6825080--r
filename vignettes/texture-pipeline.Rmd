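---
title: "Texture radiomics and SVM classification for ultrasound ROIs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture radiomics and SVM classification for ultrasound ROIs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions behind
`sonotex`: what each stage computes, which choices were genuinely open and
how they were resolved, and what the synthetic phantoms do and do not tell
you about real ultrasound data.

## 1. The analysis unit and preprocessing

The atomic unit is one 2D grey-scale image (0–255) with a binary ROI mask
of at least 16 pixels, labelled with a tissue class (malignant, benign,
fat, glandular) and a patient id. All statistics are computed over masked
pixels only; the mask's bounding-box crop keeps out-of-mask cells as
non-values that break pixel pairs, runs and zones.

**Normalization to μ ± 3σ.** The first texture-analysis step clips masked
grey values to the interval [μ − 3σ, μ + 3σ], where μ and σ are the mean
and *sample* (n − 1) standard deviation of the masked pixels. Two points
deserve emphasis:

* Clipping, not rescaling: values inside the range are untouched; outliers
  move to the nearer bound. This is the simplest reading of an intensity
  normalization "between the mean and three standard deviations", and it
  makes the operation idempotent on clip-free input.
* The σ estimator matters, because the clip bounds depend on it. We use
  the n − 1 convention of standard statistical software and state it here
  prominently; a population-σ implementation would clip slightly more.

A constant ROI (σ = 0) has no definable 6σ range and raises a
degenerate-ROI error rather than silently producing features.

**Quantization.** Grey-level matrices need a discrete alphabet. The
clipped values are binned into Ng equal-width, upper-half-open bins over
their [min, max] range, mapped to 1..Ng, with the maximum forced into bin
Ng. Ng = 64 by default — common radiomics practice for 8-bit data; it is a
free parameter (`Ng`) because the optimal alphabet depends on ROI size
(small ROIs under-populate a 64-level co-occurrence matrix). Min–max
binning makes the levels invariant under positive affine maps of the
input, which the tests assert.

## 2. The 47-feature engine

The canonical feature vector concatenates six groups (names from
`feature_names()`):

| group | count | content |
|---|---|---|
| `hist` | 4 | histogram entropy (bits), variance, skewness, excess kurtosis |
| `cooc1` | 4 | GLCM contrast, correlation, energy, homogeneity at distance 1 |
| `cooc2` | 4 | the same four at distance 2 |
| `rlm_a` | 11 | run-length features, counts summed over 4 directions |
| `rlm_b` | 11 | the same eleven, horizontal runs only |
| `szm` | 13 | size-zone features, 8-connected zones |

This 4 + 4 + 4 + 11 + 11 + 13 = 47 grouping is a deliberate, documented
convention: texture catalogues in the clinical literature often list
co-occurrence and run-length feature names twice under different matrix
headings without stating the construction, and this realisation reproduces
both the total and the duplicated-name structure with concretely different
definitions (two co-occurrence distances; two run-length direction modes).
It is our convention, declared rather than inferred — an alternative
grouping with the same total would be equally consistent with the
catalogue's ambiguity.

Conventions inside the groups:

* **First order.** Entropy uses an equal-width histogram (default: Ng
  bins) and log base 2, so a two-bin 50/50 histogram is exactly 1 bit.
  Variance/skewness/kurtosis are population central moments of the clipped
  values; kurtosis is excess (normal ⇒ 0).
* **GLCM.** Symmetric matrices (each pair counted in both orders),
  normalized to sum 1. The four per-direction matrices are *not* pooled;
  features are computed per direction and averaged, the standard Haralick
  practice. Correlation of a degenerate matrix (zero marginal variance,
  e.g. a single-level ROI) returns 0 with a warning instead of NaN so
  feature vectors stay finite.
* **GLRLM.** Maximal runs of equal level along in-mask collinear segments.
  `rlm_a` sums run counts over the four directions before computing
  features; run percentage is normalized by pixels × directions so it
  remains a fraction in (0, 1] (per single direction it is the classic
  runs/pixels ratio).
* **GLSZM.** Zones are 8-connected components of equal level (the original
  size-zone definition); 4-connectivity is available. GLV and ZSV are the
  variances of grey level and zone size under the zone-probability
  distribution.

Every matrix feature is verified against brute-force enumeration oracles
(explicit pixel-pair loops, line-walking run extraction, flood-fill zones)
on hundreds of random small ROIs at 1e-10 relative tolerance.

## 3. Machine-learning layer

**Standardization** removes the training-column mean and scales to unit
*population* variance (the StandardScaler convention: a two-point column
{1, 3} maps to {−1, +1}). Parameters are fitted on training rows only and
applied unchanged to validation rows; a leak-audit test corrupts the
validation partition and asserts the training-side transform is
bit-identical.

**Balanced binary tasks.** Task (i) pools malignant + benign against
fat + glandular; task (ii) is malignant vs benign. The majority side is
down-sampled by removing whole randomly chosen patients while a removal
still improves the image-count balance — balance is therefore as close as
whole patients allow, and no patient is partially removed.

**Patient-disjoint split.** Patients (never images) are shuffled and split
per class at the 0.8/0.2 ratio. The same grouping governs the CV folds, so
no patient's images straddle a fold boundary either.

**Grid search.** C ∈ {1, 10, 100, 1000}, γ ∈ {10⁻⁵, 10⁻⁴, 10⁻³} —
logarithmic grids spanning the stated endpoints. Mean accuracy over
patient-grouped stratified fivefold CV; ties broken towards the smallest
C, then the smallest γ, preferring the smoother model (the tie-break was
an open choice; smoothness is the conservative default).

**Probability scores.** `e1071`'s decision values are mapped through a
logistic calibration fitted on the training decision values. This keeps
scoring deterministic, exactly mirror-symmetric under label flips
(s → 1 − s), and rank-identical to the raw decision values, so AUCs are
unaffected by the calibration choice.

**RFECV.** The RBF kernel exposes no per-feature weights, so the
elimination ranking uses a linear-kernel SVM's |w| — the standard pairing
when RFE accompanies an RBF classifier, and an open choice we record
explicitly. At each step the lowest-|w| feature is dropped and
patient-grouped CV accuracy is recorded; the optimal size maximizes CV
accuracy with ties resolved towards the *smaller* set; the surviving
features are refitted with the RBF-SVM. A consequence of the smaller-set
tie-break worth knowing: once CV accuracy saturates at 1.0 (easy
problems), the RFS collapses to the few features that already achieve
ceiling. The feature-recovery experiments in the test suite are therefore
designed in the regime RFECV is actually for — five informative features
with unit-sized (1 SD) standardized effects among 42 pure-noise features,
15 patients × 3 images per group — where single features are individually
weak and the accuracy optimum genuinely needs most of the informative set.

## 4. Evaluation statistics

* **AUC** is the Mann–Whitney statistic (ties weighted ½), identical to
  the trapezoidal area under the empirical ROC. The 95% CI uses the DeLong
  placement-value variance applied on the logit scale, keeping bounds in
  [0, 1]; degenerate AUCs of exactly 0 or 1 fall back to a clamped
  normal-scale interval.
* **DeLong comparison** of two ROC curves over the same samples uses the
  covariance of paired placement values and a two-sided normal test.
  Identical score vectors return Δ = 0, p = 1; zero variance with non-zero
  Δ is an error with a diagnostic, not a silent p-value. Both the variance
  and the paired p-value are cross-checked against an independent
  reference implementation at 1e-10, and the test's type-I error is
  simulation-calibrated to the nominal 5%.
* **ICC** is fixed to ICC(2,1) — two-way random effects, absolute
  agreement, single measurement — computed from ANOVA mean squares, with
  the standard F-based CI. The model choice was open (the verbal
  interpretation scale does not pin down an ICC form); absolute agreement
  is the appropriate form for "would a second reader produce the same
  number", which is the question asked of two-reader delineations. Verbal
  categories: ≤ 0.40 poor/fair, 0.41–0.60 moderate, 0.61–0.80 substantial,
  0.81–1.0 almost perfect.
* **Per-feature tests.** One-way ANOVA F across the four classes with the
  fixed significance gate p < 1e-4 (the Bonferroni-style rule stated with
  the method), and pooled-variance two-sided t tests for the two-group
  comparison. Degenerate inputs follow documented conventions (both
  variances zero ⇒ p = 1).

## 5. The synthetic cohort generator

Real ABUS data cannot ship with the package, so the generator emulates the
statistical structure the pipeline relies on:

* **Speckle model.** Gamma-distributed multiplicative noise (shape =
  `skew_shape`, unit mean) smoothed by a Gaussian kernel (SD =
  `correlation_length_px`), affinely mapped to mean `mean_level` and SD
  `contrast_scale`, clipped to [0, 255] and rounded. Gamma speckle is the
  standard ultrasound intensity model and gives direct control of
  histogram skewness — mirroring the empirical finding that histogram
  shape (skewness/kurtosis) separates all four tissue classes. Note that
  Gaussian smoothing attenuates skewness by roughly the square root of the
  kernel's effective pixel count, so the per-class skewness ordering is
  cleanly attributable to `skew_shape` only when correlation lengths are
  comparable; the ordering test in the suite holds correlation length
  fixed for exactly this reason.
* **Default classes.** Malignant: dark (mean 60), coarse (corr. length
  3 px), heavily skewed (shape 0.7) — the hypoechoic, shadowing phenotype;
  benign: mean 110, 1.5 px, shape 2; fat: mean 150, 4 px, shape 5;
  glandular: mean 190, 1 px, shape 10. These were chosen once as a
  strongly separated, clinically plausible parameterisation (echogenicity
  ordering fat < glandular is deliberate on the grey scale; what matters
  is separation, not absolute levels) and are the fixed study conditions
  for all recovery tests.
* **Cohort structure.** Lesion patients carry one lesion rendered as a
  perturbed-ellipse blob (star-convex, hence 8-connected; never touching
  the border so all matrix directions are defined) composited into a
  neutral background field, with 2–16 images per lesion drawn uniformly;
  tissue patients carry 2 whole-field images with a large interior
  rectangular mask — mirroring clinical series where lesions contribute a
  handful of images each and tissue ROIs are single large areas. A second
  reader is simulated by dilating or eroding the true mask by one pixel.
* **What it does not emulate.** Beam physics, attenuation, shadowing,
  depth-dependent gain, 3D volume context, reader-dependent boundary
  semantics, or intra-patient lesion heterogeneity (images of one lesion
  are independent draws). Passing recovery tests therefore demonstrate the
  *pipeline's* correctness and calibration, not clinical performance;
  real-data AUCs cannot be inferred from phantom AUCs.

Everything is bit-reproducible: a cohort spec plus seed fans out to
per-image sub-seeds through a fixed counter scheme, and the experiment's
master seed derives per-stage seeds the same way (the scheme is a linear
congruential map kept below 2³¹).

## 6. Problem sizes and numerical conventions

The shipped tests and the acceptance script use desk-scale problem sizes
chosen to exercise every code path with comfortable statistical margins:
64 × 64 images, 20 patients per class for the main recovery experiment
(≈ 500 images), 8–15 patients per class for the null-calibration and
RFECV-recovery experiments, 200 random ROIs for the oracle sweep, and 500
replicates for the DeLong type-I simulation. Tolerances: 1e-10 relative
for oracle equivalence, 1e-9 for standardization moments, 1e-10 against
the external ROC reference. Degenerate cases (constant ROIs, zero-variance
matrices, single-class inputs, empty partitions) raise classed errors
(`sonotex_parameter_error`, `sonotex_degenerate_roi`) rather than
propagating NaN.

## 7. Known limitations

* The 47-feature grouping is one defensible reading of an ambiguous
  catalogue (see §2); feature values are not IBSI-certified, though the
  definitions follow the standard Haralick/Galloway/Thibault forms.
* Quantization (Ng, binning rule) is a convention the upstream description
  leaves open; results depend on it, which is why it is a parameter.
* The null-calibration guarantee is about the across-seed mean of
  validation AUC; any single small validation set has wide chance
  variation.
* Only binary tasks are supported; multi-class ROC is out of scope, as are
  oversampling techniques and classifiers other than the SVM.
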