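---
title: "Modeling acute radiation esophagitis risk from multi-omics features: methods"
author: "esotox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling acute radiation esophagitis risk from multi-omics features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Grade ≥ 2 acute radiation esophagitis (ARE) is a common, debilitating toxicity
of thoracic chemoradiotherapy. Its pretreatment prediction from the planning
CT, the 3D dose distribution, and the esophagus contour is a normal-tissue
complication modeling task with three candidate information sources:

* **clinical factors** (chemotherapy regimen, stage, prescription dose, ...),
* **radiomics** — intensity and texture statistics of the esophagus on CT,
* **dosiomics** — the same texture machinery applied to the 3D dose, plus
  dose-volume histogram (DVH) metrics and spatial dose moments.

`esotox` implements the complete analysis pipeline — feature extraction,
bootstrap stability feature selection, imbalance-aware easy-ensemble ridge
classification over repeated stratified train–test splits, and nomogram
export — together with a synthetic phantom cohort generator, so every stage
is testable end to end without any patient data.

## Phantom cohorts

`phantom_config()` describes one synthetic study. The defaults are the
conditions the pipeline is designed for:

* 1 mm isotropic grids (`grid_shape = c(40, 40, 100)`), the smallest grid
  holding the organ with a margin;
* a tubular esophagus of radius 11.5 mm and length 90 mm — an analytic
  volume of π r²L ≈ 37.4 cc, matching the ~37 cc organ the contouring
  convention produces;
* CT texture inside the mask: a Gaussian random field (white noise smoothed
  with a separable Gaussian kernel of the configured correlation length,
   3 mm by default, truncated at 2σ), scaled to sd 40 HU around a mean of
  40 HU and clipped into the [−150, 180] HU window. Per patient, the
  correlation length and mean are jittered (log-normal sd 0.3, normal
  sd 10 HU) so texture features vary *between* patients — fixed-bin-count
  discretization makes texture features insensitive to a pure intensity
  rescale, so the texture *scale*, not amplitude, is what must vary;
* air cavities: 2% of mask voxels set to −1000 HU, which the HU-window mask
  refinement removes, exactly as intraluminal air is removed on real CT;
* dose: prescription (drawn per patient from a 45–70 Gy distribution with
  median 60 Gy) × a lateral Gaussian falloff (40 mm scale) + a longitudinal
  gradient (2 Gy/cm) + voxel noise (1 Gy), floored at 0. Falloff and
  gradient carry per-patient log-normal jitter (sd 0.25) so dose-shape
  features vary between patients;
* cohort size 161 with a target event prevalence of 31.7%.

Outcomes follow a logistic model in standardized planted feature values.
`calibrate_intercept()` simulates `n_mc ≥ 1000` cases, standardizes the
planted features by their Monte-Carlo means/SDs, and bisects the intercept
until the expected event rate (the mean of the per-case probabilities, i.e.
the Monte-Carlo label rate with Bernoulli noise integrated out) is within
0.001 of the target; with no planted effects the closed form
`qlogis(target)` is used. Seeds derive from one master seed by a counter
scheme (`derive_seed`), so cohorts are extensible without reshuffling and
label draws use an independent stream.

What the phantom deliberately does **not** emulate: anatomy (mediastinal
neighbours, organ curvature), CT acquisition physics (beam hardening,
partial-volume slices), realistic IMRT fluence patterns, or any correlation
between clinical covariates and outcome (clinical factors are drawn from
realistic marginals but carry no planted effect — mirroring their weak
predictive value in this setting). A pipeline that passes the phantom tests
is verified as *machinery*; its clinical validity on real cohorts is a
separate question the package makes no claim about.

## Feature extraction

Volumes are resampled to 1 mm isotropic grids (trilinear for intensities,
nearest-neighbour for masks) and the esophagus mask is refined by the closed
HU window [−150, 180] before any extraction; by default the refined mask is
used for both CT and dose features (`hu_window_scope = "both"`).

**Radiomics** (`extract_radiomics`): per image variant — original, the eight
sub-bands of a single-level undecimated separable Haar wavelet, and
Laplacian-of-Gaussian at σ ∈ {1, 2, 3} mm — a 12-statistic first-order block
plus, per bin count in {20, 30, 40, 50, 80, 100, 150, 200, 250, 300},
entropy and the GLCM (6 features) and GLRLM (7 features) texture families.
Discretization uses equal-width bins by *count* over the in-mask range, the
maximum mapping to the top bin. Texture matrices are accumulated over the 13
unique 3D directions at distance 1 and features are averaged across
directions (so 90° grid rotations leave them unchanged). The feature count
is the documented formula `n_variants × (12 + |bins| × (1 + 6 + 7))` and is
tested, not asserted as a constant; no attempt is made to reproduce any
particular historical feature count, since full extractor configurations are
rarely recoverable from publications. Haar was chosen as the short symmetric
orthogonal wavelet; the LoG is implemented as separable Gaussian smoothing
followed by the 6-neighbour discrete Laplacian (no σ² scale normalization —
the scale response enters through the σ grid).

**Dosiomics** (`extract_dosiomics`): three blocks.

1. *Scale-invariant 3D dose moments*: with physical-mm coordinates about the
   dose-weighted centroid,
   `eta_pqr = mu_pqr / mu_000^(1 + (p+q+r)/3)` for all per-axis orders 0–3
   except (0,0,0) — 63 features. The exponent is the classical 3D
   scale-invariant normalization: resampling the grid leaves η unchanged
   (tested at < 2% drift for a smooth field under 1 mm → 2 mm downsampling).
   Note that η is *not* invariant under dose-amplitude scaling; it is
   homogeneous of degree −(p+q+r)/3 in the amplitude
   (`eta(kD) = k^(−(p+q+r)/3) eta(D)`), and the test suite asserts that
   exact covariance.
2. *DVH metrics*: a cumulative histogram at 0.01 Gy resolution; `vx()`
   returns the (interpolated) volume in % and cc receiving more than x Gy,
   `dx()` the largest dose still covering x% of the volume. The default Vx
   grid is {0.99, 1, 6, …, 66} Gy — the sub-Gy query exists because
   fractional-Gy thresholds such as V0.99 appear in practice; it is read as
   a Gy threshold (the volume-fraction reading is available through `dx`).
3. *Dose texture*: the radiomics first-order + GLCM/GLRLM operators on the
   original dose grid, names prefixed `dose_` so they can never collide with
   CT features.

## Feature selection

`select_features()` implements stability screening:

1. **Bootstrap screen** — 100 stratified subsamples of 70% of patients; a
   feature survives an iteration iff its subsample variance is positive and
   its one-way ANOVA F-test p ≤ 0.1 against the label. Stratification keeps
   both classes in every subsample so the F-test is always defined.
2. **Frequency filter** — keep the top 10% most frequently surviving
   features (among those surviving at least once), with a floor of 10; ties
   break by (frequency, median p, name), so the ranking is deterministic.
3. **Correlation pruning** — greedy scan in rank order, dropping any feature
   with |Pearson r| > 0.5 against an already-kept one (the higher-ranked
   member of a violating pair survives).
4. **CV prefix search** — nested prefixes of the ranked list are scored by
   ridge AUC over 20 repetitions of stratified 5-fold CV, one pooled
   out-of-fold AUC per repetition. The returned subset is the smallest
   prefix within one standard error of the best, where the error unit is
   the SD of a *single repetition's* estimate. A band that shrinks with the
   number of repetitions (SD/√20) would defeat the parsimony rule: on
   feature tables with no real signal, noise features still carry in-sample
   spurious associations that persist across fold re-randomizations, so
   between-prefix differences never shrink with more repetitions. Even with
   this band, a pure-noise table can legitimately return more than one
   feature — spurious in-sample association is real association *in that
   sample*; only held-out evaluation (next section) reveals it as noise.

## Modeling and evaluation

`train_ensemble()` is the core fit: a ridge classifier (closed-form
least-squares on ±1 labels with unpenalized intercept, standardization from
training rows only) wrapped in an easy-ensemble. The penalty is chosen from
13 log-spaced values 10⁻³…10³ by tenfold stratified CV AUC on the training
cohort. Each of 10 bags takes a stratified 2/3 subsample of the training
patients and balances it — all minority-class patients plus an equal-count
draw from the majority class — so every bag sees a balanced problem while
the ensemble still sees most of the majority class. The ensemble score is
the mean bag margin; a univariate logistic calibration fitted on training
scores maps margins to probabilities (a margin classifier needs an explicit
calibration step to speak in probabilities). Accuracy uses the 0.5
probability threshold.

`repeated_splits()` runs 30 independent stratified 2/3–1/3 partitions (161
patients → 107 training / 54 testing, event fractions matched within one
patient) and records AUC (rank-based, ties at 1/2) and accuracy on both
cohorts. **Feature selection is re-run inside every split on its training
cohort only.** Selecting once on the full cohort and then splitting — a
sequence sometimes seen in applied work — leaks the test patients'
correlations into the feature set: on null phantom cohorts it inflates mean
test AUC to ≈ 0.67 where chance is 0.5 (measured by this package's own null
experiment). With per-split selection the null pipeline sits at ≈ 0.49.
The cohort-level selection report is still produced as the descriptive
artifact (bootstrap frequencies, pruning decisions, final subset).

`summarize_metric()` reports mean ± SD over splits with the 95% normal
CI of the mean (±1.96 SD/√n). `compare_models()` is a two-sided paired
t-test over shared splits, with a sign-flip permutation alternative; exactly
constant nonzero differences fall back to the exact sign test.

`combine_models()` averages all split models in raw feature space — the
mean of linear functions is linear, so the combined score is *exactly* the
mean of the individual model scores, even when splits selected different
feature subsets (absent features contribute zero coefficients). The
RadScore is the calibrated logit `a + b·(intercept + Σ coef_j x_j)`; event
probability is its logistic. `build_nomogram()` tabulates, per feature, the
coefficient, the cohort-mean reference (0 points), the observed axis range
and points-per-unit, scaled so the observed cohort RadScore range spans
0–100 total points; the total-points axis maps to probability through the
logistic, and a nomogram read-off reproduces the model probability to
within the interpolation error of the table (≤ 0.01).

## Numerical choices and problem sizes

* Texture matrices are computed from cached per-patient direction
  structures (co-occurring voxel-index pairs; line decompositions for runs),
  so repeated bin counts and image variants reuse the geometry.
* Ridge systems are solved by Cholesky-backed `solve()` on p ≤ ~20 features;
  the independent check in the tests is numerical minimization of the
  penalized objective.
* Phantom generation holds at most one patient's volumes in memory when
  streaming features (`simulate_features`), which keeps a 161-patient
  cohort extraction to well under a minute.
* The test suite runs the full signal-recovery experiment at study scale
  (161 patients, prevalence 0.317, ten master seeds, 30 splits each) with a
  deliberately lean extraction configuration (original-image GLCM at bin
  counts 20 and 50 plus the full dosiomics block, ~150 features): planted
  effects live in that configuration, and the scientific claims under test
  (signal recovery, null calibration, split geometry) do not depend on the
  width of the feature table. Unit tests use a smaller 6 mm × 30 mm tube
  phantom where the organ's exact size is irrelevant.
* Prevalence checks use three cohorts of 500 patients; the calibration
  itself uses 1000 Monte-Carlo cases.

## Known limitations

* The phantom's texture/dose models are separable and stationary; real
  esophagus CT and IMRT dose are neither. Passing tests demonstrate the
  pipeline's correctness and statistical calibration, not clinical
  performance.
* GLSZM/NGTDM texture families and shape features are not implemented; the
  texture surface is GLCM + GLRLM.
* The nomogram is exported as a table plus probability map (with a minimal
  base-graphics `plot` method); no publication-grade nomogram rendering.
* With per-split selection the 30 split models can differ in their feature
  sets; the combined model and nomogram live on the union, which makes the
  pooled coefficients conservative (features selected rarely get shrunk
  toward zero by the averaging).
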