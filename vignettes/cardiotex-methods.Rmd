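---
title: "Radiomics texture analysis and ensemble scoring for LV remodeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics texture analysis and ensemble scoring for LV remodeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Chronic arterial hypertension remodels the left-ventricular (LV) myocardium
— fibrosis, myocyte hypertrophy, architectural distortion — in ways that are
largely invisible to the eye on cardiac CT but may leave a quantitative
signature in the image texture. `cardiotex` implements a complete radiomics
pipeline for this setting: a polygonal LV region of interest (ROI) on a 2-D
gray-level image is normalized, 377 texture and shape descriptors are
extracted, a zoo of eleven classifiers is trained to separate hypertensive
(HTN) from control (NC) subjects, the classifiers are fused into a single
per-subject ensemble machine-learning (EML) score, and the score is
validated against interventricular septum width, a standard surrogate of LV
remodeling. A synthetic cohort generator reproduces the statistical
structure of such a study so the whole pipeline is testable without any
patient data.

# Gray-level normalization

Each ROI is normalized independently with the μ ± 3σ rule: with μ and σ the
mean and standard deviation of the pixel values inside the ROI, values are
clipped to `[μ − 3σ, μ + 3σ]` and mapped linearly to integer levels
`1..Ng`:

```
level = 1 + floor((clip(v) − (μ − 3σ)) / (6σ) · Ng),   level(μ + 3σ) = Ng
```

This removes per-image brightness and contrast variation; any affine
transform `a·I + b` (a > 0) of the input yields bit-identical levels.
Design choices worth stating explicitly:

* **Quantization depth.** `Ng = 64` for the co-occurrence, run-length,
  autoregressive and wavelet families; `Ng = 256` for histogram and
  gradient statistics. Both are configurable in `extract_all()`.
* **Degenerate input.** A constant ROI (σ = 0) maps every pixel to level
  `⌈Ng/2⌉` with a warning rather than an error.
* **Per-ROI, not per-image.** Pixels outside the ROI never influence μ, σ,
  or any feature.
* **Rasterization.** Pixel centers sit at `(i + 0.5, j + 0.5)`; a pixel
  belongs to the ROI when its center is inside the polygon under the
  even-odd rule. This convention is unambiguous and directly checkable
  against a brute-force point-in-polygon test.

# The 377-feature manifest

The feature vector is fixed by a versioned manifest (`manifest_v1`,
`feature_manifest()`):

| family | count | notes |
|---|---|---|
| histogram | 9 | mean, population variance, skewness, excess kurtosis, nearest-rank percentiles 1/10/50/90/99 |
| gradient | 5 | central-difference magnitude on interior pixels; `GrNonZeros` = fraction nonzero |
| co-occurrence | 220 | 11 Haralick statistics × 5 distances × 4 directions `(d,0),(0,d),(d,d),(d,−d)` |
| run-length | 20 | 5 statistics × 4 directions, runs truncated at the mask boundary |
| autoregressive | 5 | causal AR fit (left, upper-left, upper, upper-right), `Teta1..4` + residual `Sigma` |
| wavelet | 20 | orthonormal Haar subband energies `LL/LH/HL/HH` at scales 1–5 |
| geometry | 98 | mask-only shape descriptors (area, perimeter, moments, Feret widths, radial signature, projections) |

Naming follows the MaZda convention (`S(1,0)DifEntrp`, `Horzl_RLNonUni`,
`WavEnLH_s-4`, `GeoEl`, ...), so feature names from the published selected
list appear verbatim. The geometry family beyond area, elongation and the
moment invariants is a documented reconstruction: the closed-source
reference software does not publish definitions for descriptors such as
`GeoSxL`, `GeoW3`, `GeoW5b` or `GeoW12`, so this package assigns them
well-defined analogues (bounding-box area, Feret diameters at 15° steps and
their perimeter-normalized variants) under the same names and makes no
claim of numeric agreement with the reference binaries. Entropies use the
natural logarithm with `0·log 0 = 0`; co-occurrence matrices are symmetric
and pairs crossing the mask boundary are discarded.

A feature undefined for a ROI — a wavelet scale whose dyadic support
nowhere fits inside the mask, an AR fit with fewer than 20 supported
pixels, a gradient on a ROI with no interior pixel — is recorded as
missing (`NA`) and handled by the screening stage, never silently imputed
at extraction time.

# Screening, scaling and the classifier zoo

Screening runs on the training split only and removes a feature when (a)
its absolute Pearson correlation with the binary label is below `1e-5` or
above 0.95, (b) more than 90% of its values are identical, or (c) any value
is missing. Autoscaling (mean 0, sample SD 1) is learned on the training
split and applied frozen to the test split; a test value missing for a
feature that passed screening is imputed at the training mean (0 after
scaling). No test information reaches screening, scaling, tuning or model
selection.

The zoo trains eleven model families, mapped to standard R backends:

* PLS-DA (`mixOmics::plsda`), NB (`e1071::naiveBayes`), DT (`rpart`),
  RF (`ranger`, probability forests), GBT (`xgboost`),
  SVM and FLM (`e1071::svm`, radial and linear kernels, Platt
  probabilities).
* GLM and LR are realized as elastic-net (α = 0.5) and ridge (α = 0)
  penalized logistic regressions via `glmnet`. After screening the problem
  still has more features than training subjects, so an unpenalized
  logistic fit is degenerate; a light ridge penalty is the standard remedy
  and plays the role the reference platform's regularized defaults played.
* DL and aNN are single-hidden-layer feed-forward networks (`nnet`) with
  different capacity/decay. No multi-layer perceptron backend is available
  in the dependency set, so "deep" here means a larger single hidden layer
  — documented rather than hidden.

Hyperparameters come from small per-model grids ranked by stratified
k-fold cross-validation accuracy on the training split (10-fold by
default; the tuning budget caps how many grid points are tried). Every
model returns a per-sample predicted class and a confidence — the
predicted-class membership probability in `[0.5, 1]` — because the
ensemble needs a comparable confidence from every member. A model that
fails to fit is recorded with a failure status and excluded downstream.

# The EML score

Models whose cross-validation accuracy strictly exceeds 60% are selected;
their cross-validation accuracy is also the vote weight. The published
description leaves open whether the gate and weight use cross-validation
or test accuracy; this package defaults to cross-validation accuracy (the
only choice that never touches the test labels) and exposes
`weight = "test_accuracy"` as an option. For each test sample the score is

```
EML(x) = Σ_m s_m(x) · acc_m · conf_m(x),   s_m = +1 if model m votes HTN, −1 if NC
```

The operating cutoff maximizes Youden's J = sensitivity + specificity − 1
over the midpoints between adjacent sorted unique scores (plus sentinels
below and above all scores), breaking ties toward the larger cutoff
(higher specificity). The cutoff is derived on the test scores, where the
confusion matrix is also reported. The ROC AUC is the Mann–Whitney
statistic (ties ½) with a DeLong placement-value standard error and a
two-sided normal p-value against AUC = 0.5. The score–septum-width
association is an ordinary Pearson correlation (R² = r², t-based p on
n − 2 df) over the test samples.

Two structural properties are tested rather than assumed: unanimous
confident votes force `sign(score)` to the consensus class, and rescaling
all vote weights by c > 0 rescales scores by c without changing AUC,
cutoff classifications, or r.

# Shadow-feature relevance selection

The relevance stage is a from-scratch Boruta-style loop: each iteration
appends a shadow copy of the feature table (every column independently
permuted, doubling the width), trains a random forest on the combined
table, and flags a real feature as a hit when its impurity-decrease
importance strictly exceeds the maximum importance among all shadow
columns. Hits accumulate over `n_iter` fresh-shadow iterations (the
reference analysis used 2000; desk-scale runs default to 200).

Aggregation into a final decision is not specified by the reference
description, so the canonical Boruta rule is adopted: a feature is
confirmed when its hit count beats a fair coin by a two-sided exact
binomial test at α = 0.01, Bonferroni-corrected over features, and
requires more hits than misses; a plain hit-fraction > 0.5 rule is
available as `rule = "fraction"`. There is no "tentative" state. The
forest backend (`ranger`) provides Gini impurity-decrease importance;
the entropy-criterion variant of "information gain" is not available in
any installed backend, and Gini impurity decrease is used as the
information-gain-style importance throughout.

# Group statistics and the smile table

* Normality: D'Agostino–Pearson omnibus K² (D'Agostino's skewness z,
  Anscombe–Glynn kurtosis z, χ² with 2 df), implemented from the published
  transformations and validated against an independent implementation;
  requires n ≥ 20. Normality results are reported but do not gate the
  t-tests, mirroring the reference analysis.
* Group tests: pooled-variance Student t (also available directly from
  printed group summaries via `ttest_summary()`), Benjamini–Hochberg FDR
  (via `p.adjust`), and Yates-continuity-corrected χ² for 2×2 tables —
  the continuity correction reproduces the published clinical p-values
  (0.038 for sex, 0.006 for diabetes), where the uncorrected test does
  not.
* Smile table: per-feature fold change FC = mean(HTN)/mean(NC) on the raw
  (un-autoscaled) feature scale — autoscaled means are 0 and FC would be
  undefined — with `log2(FC)` against `−log10(BH-adjusted p)`. "Two-fold"
  means FC ≥ 2 or ≤ ½. Features with a non-positive class mean get an
  undefined FC and are flagged rather than dropped.

# The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` simulate the statistical structure
the analysis assumes:

* **Calibration.** Septum width is drawn from the published group
  summaries (HTN 10.01 ± 2.7 mm, NC 8.15 ± 1.66 mm, truncated at 0); ROI
  pixel area and second-moment elongation from the published `GeoF`
  (3495 ± 1246 vs 2515 ± 736 px) and `GeoEl` (2.17 ± 0.82 vs 1.55 ± 0.48)
  summaries; clinical covariates (age, BMI, sex, diabetes, dyslipidemia)
  from the published marginals, with BMI truncated to [12, 60] and age
  > 18. Geometry scales with image area so smaller images keep the same
  relative footprint.
* **Texture.** The ROI interior is a Gaussian random field with a
  class-specific correlation length (Gaussian-kernel smoothed white
  noise; length 1 = white noise) on a 16-bit gray-level scale. The HTN
  class gets a longer correlation length, and every subject draws an
  individual correlation length (SD 0.35 px) — without subject-level
  texture variability the classes would be trivially separable and the
  ensemble score would saturate, which no real cohort does.
* **Severity coupling.** A per-subject latent severity draws septum width
  and (with correlation `severity_rho`, default 0.5) the subject's
  geometry and texture deviations. A cohort in which septum width is
  connected to the image only through the class label cannot produce a
  score–septum correlation much above ~0.2, far below the association the
  analysis is designed to detect, so within-class coupling is part of the
  emulated structure. Marginal distributions are unaffected.
* **Effect size.** `effect_size` interpolates every class contrast between
  0 (identical classes, the null configuration) and 1 (the calibrated
  contrast); it is exposed as a free parameter because the reference
  tables report feature-level group means, not a generative effect size.
  In the package's own checks "moderate effect" means `effect_size = 0.5`,
  which lands the ensemble AUC near the published 0.73.
* **What it does not emulate.** Real CT physics (beam hardening, contrast
  dynamics, reconstruction kernels), 3-D anatomy and cardiac phase,
  radiologist segmentation variability, and covariate–covariate
  correlations beyond the severity coupling. Passing tests therefore
  demonstrate the correctness and statistical behavior of the pipeline,
  not clinical performance on real cohorts.

The generator is seed-deterministic (bit-identical cohorts from identical
spec + seed) and restores the session RNG state on exit. Polygons are
star-shaped radial perturbations of an ellipse (24 vertices), guaranteed
simple; ROIs that would not fit the image raise a geometry error, and the
per-subject area is capped so the wobbled major axis keeps a margin inside
the frame.

# Numerical conventions and degenerate inputs

* Sample (n − 1) SD in normalization and autoscaling; population moments
  in histogram/gradient statistics; skewness and excess kurtosis defined
  as 0 for zero-variance input.
* Nearest-rank percentiles: `x_(⌈p·n⌉)`.
* Co-occurrence correlation is defined as 0 when a marginal SD is 0
  (single-level ROI).
* Aliased (collinear) AR coefficients are reported as 0; `Sigma` is the
  RMS residual.
* Wavelet subband letters are ordered (x-filter, y-filter): `LH` responds
  to variation down the rows. A coefficient at scale s is supported only
  if its full 2^s × 2^s dyadic block lies inside the mask.
* The 70:30 split stratifies by class with half-up rounding per class
  (158 subjects → 111 train / 47 test).
* Derived stage seeds are produced by a small LCG-style map kept below
  2^31.

# Problem sizes used in the packaged checks

The test-suite and acceptance-script runs use cohorts of 83 + 75 subjects
at 64 px for replicate-based checks (20 moderate-effect replicates, 5–10
null replicates), 128 px for the single full-scale run, 3-fold
cross-validation with a tuning budget of 1, 100–200 trees per forest, and
200 shadow-feature iterations (50 in the null arm). These sizes are the
package's chosen desk-scale operating point: large enough for the
statistical properties under test to hold with margin, small enough to
keep a full run on a single CPU comfortable.

# Known limitations

* Geometry descriptors without published definitions are reconstructions;
  numeric equality with the closed-source reference tool is out of scope.
* The ensemble's probability calibration is whatever each backend
  provides (Platt scaling for SVMs, raw class probabilities elsewhere);
  no recalibration is applied.
* No nested cross-validation: the reported cross-validation accuracy of a
  tuned model is the selected grid point's score.
* Boruta here is two-state (confirmed/rejected); the three-state variant
  with tentative features is intentionally not implemented.
* The DeLong machinery covers a single ROC curve; paired two-curve
  comparison is not implemented.
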