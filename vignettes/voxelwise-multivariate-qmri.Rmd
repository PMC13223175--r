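---
title: "Voxelwise multivariate analysis of multimodal quantitative MRI maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise multivariate analysis of multimodal quantitative MRI maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxmanova)
```

## The problem

Quantitative MRI multiparameter mapping yields several co-registered
parameter maps per subject — magnetization transfer saturation (MTsat,
myelin-sensitive), proton density (PD, free-water-sensitive), and the
relaxation rates R1 and R2\* (the latter iron-sensitive). Age affects these
tissue properties jointly: iron accumulates while myelin degrades, often in
the same structures and with opposite signs across maps. Testing each map
separately (a univariate GLM per voxel, per modality) can miss such
coordinated change; a per-voxel multivariate GLM (MANOVA) tests all
modalities at once.

`voxmanova` implements that mass-multivariate pipeline end to end:
standardization, per-voxel univariate and multivariate GLMs, Wilks' lambda
inference, canonical decomposition of the multivariate effect, family-wise
error (FWER) control, comparison of thresholded maps, split-half
cross-validation, and ROI-level partial correlations — together with a
synthetic phantom generator so that every stage runs and is testable at
desk scale without any imaging data.

## The model

At each voxel, the n subjects' values on the p = 4 modalities form
`Y (n x p)`, modelled as

```
Y = X B + E
```

with a shared design matrix `X (n x k)`: an intercept column followed by
mean-centred age, total intracranial volume (TIV), gender and scanner
(`k = 5`). `B (k x p)` is estimated by ordinary least squares via the QR
decomposition of `X` (numerically equivalent to the normal equations to
better than 1e-8, which the tests verify). Residuals are formed per voxel,
giving each voxel its own error covariance
`Sigma_hat = E_hat' E_hat / (n - k)` — covariance is assumed common across
subjects, not across voxels.

A hypothesis is the double contrast `C B L = 0`: `C (c x k)` picks
regressors, `L (p x l)` picks modalities. The age effect across all maps
uses `C = [0 1 0 0 0]` and `L = I_4`. Inference is through Wilks' lambda,

```
lambda = det(E_sscp) / det(E_sscp + H)
H      = (C B L)' [C (X'X)^-1 C']^-1 (C B L)
E_sscp = L' E_hat' E_hat L
```

For a single-row contrast the transform
`F = ((1 - lambda)/lambda) * (n - k - l + 1)/l` is exactly
F-distributed with `(l, n - k - l + 1)` degrees of freedom — `(4, 130)` at
n = 138, k = 5, l = 4. Multi-row contrasts use Rao's F approximation
(with `t = 1` when its radicand's denominator vanishes), exact whenever
`c = 1` or `l <= 2`.

The canonical decomposition solves `H v = lambda_i E_sscp v`; eigenvectors
(sorted by descending eigenvalue) express each modality's contribution to
the effect. Wilks' lambda factorizes as `prod(1 / (1 + lambda_i))`. The
number of possible variates is the smaller of the number of tested
dependent variables and the number of non-intercept regressors (4 here),
while a rank-c hypothesis has exactly c nonzero eigenvalues. Because the
vectors derive from an F-type statistic their signs are not interpretable,
so reports use absolute weights.

### Normalization choices

Each modality has its own physical units, so maps are z-scored per voxel
across subjects (n − 1 denominator) before analysis. Two facts justify
this: the multivariate statistic is invariant to any invertible linear
mixing of the modalities (verified to 1e-8 in the tests), and the
univariate F is invariant to positive rescaling. Voxels whose
across-subject standard deviation falls below `sd_floor = 1e-8` are
removed from the valid mask rather than zero-filled — a constant column
would be degenerate for the error SSCP and would distort cluster
bookkeeping. The analysis mask is the intersection of the tissue mask with
all four modalities' valid masks, so `Y` is complete at every analyzed
voxel.

Canonical weight vectors are normalized to unit Euclidean norm by default
(absolute weights then fall in [0, 1] and are scale-free); statistical
standardization against the error covariance (`v' Sigma v = 1`) is
available via `normalize = "error"`. The choice does not affect which
modality dominates.

## FWER control

Voxel-level family-wise error control is provided two ways:

* `fwer_voxel_bonferroni()` — significant iff
  `p < alpha / (#mask voxels)`. Fast, valid, conservative under the
  positive dependence created by smooth maps.
* `fwer_permutation_maxstat()` — the default scientific choice: the null
  distribution of the *maximum* statistic over the mask is estimated by
  subject-level permutations applied jointly to all modalities (preserving
  the cross-modality covariance under the null). The default
  Freedman-Lane scheme permutes reduced-model (nuisance-only) residuals
  around the reduced fit, preserving the nuisance structure; simple
  permutation of the data rows is available for comparison. A voxel's
  FWER-corrected p-value is `(1 + #{null max >= stat}) / (n_perm + 1)`.

Random-field-theory FWER (the classic parametric mechanism in SPM) is
deliberately not implemented: it requires smoothness estimation and offers
no additional inferential content at phantom scale, while permutation
control is exact under exchangeability. Consequently cluster/voxel counts
on real data thresholded with RFT software are approximated, not
reproduced bit-for-bit.

When the same univariate inference is run on the four modality maps, the
family alpha is Bonferroni-divided across maps: `0.05 / 4 = 0.0125` per
map. Thresholded maps are labelled into connected components (default
connectivity 18 — faces + edges, common practice; 6 and 26 available) and
summarised as cluster count, size range and total voxels. No cluster
extent threshold is applied, so size-1 clusters are reported.

## Map comparison and cross-validation

The four thresholded univariate maps are aggregated by voxelwise union.
Agreement between the multivariate map and that union is quantified with
Cohen's kappa, computed within the analysis mask only — including the vast
empty background would inflate chance-corrected agreement given how sparse
significant voxels are. `split_half()` divides subjects into two disjoint
halves (stratified by age quintile and scanner by default, so both halves
span the age range; plain random splitting by flag) and
`crossval_report()` reruns the entire pipeline — including
re-standardization — within each half.

## ROI analysis

For each region of interest, per-subject medians of the standardized maps
are extracted, gender, TIV and scanner are regressed out of both the
medians and age (Frisch-Waugh partialling; identical to textbook partial
correlation, which the tests check against an inverse-correlation-matrix
oracle), and the Pearson correlation of the residuals is reported with its
Fisher z transform `atanh(r)`. The z standard error defaults to
`1 / sqrt(n - 3)` — at n = 138 this gives 0.086, matching the conventional
report; the covariate-adjusted `1 / sqrt(n - g - 3)` (0.087 at g = 3) is
available by flag, and the p-value uses `df = n - 2 - g`. Multi-part ROIs
are supported as label-set unions. `peak_canonical_vector()` reports the
absolute canonical weights at the ROI's peak-F voxel — a peak-voxel
property, not an ROI-wide contribution.

## The synthetic phantom

`generate_covariates()` draws ages from a truncated normal (defaults: range
19-75, mean 46.64, sd 21) with 35.5% males, TIV ~ N(1450, 130) mL, and two
balanced scanners (each guaranteed >= 2 subjects when n >= 4). Real aging
cohorts are often bimodal in age, so a young/elderly two-component mixture
mode is provided; the truncated normal is the default because linear-model
validation does not require bimodality. The number of scanners and their
split are not constrained by the cohort description, so two balanced
scanners is a flagged assumption.

`generate_maps()` instantiates the linear model spatially: inside each
designated region, `baseline + age_slope * (age - mean) + tiv_slope *
(TIV - mean) + gender/scanner offsets + noise`; elsewhere, noise only.
Noise is drawn i.i.d. across voxels and subjects with a full cross-modality
covariance `diag(sd) %*% corr %*% diag(sd)`, then each modality volume is
Gaussian-smoothed (separable kernel, truncated at 3 sigma, zero padding) —
spatial correlation arises solely from this smoothing, the simplest
generator with controllable smoothness. Smoothing is plain Gaussian rather
than tissue-weighted: the phantom emulates the end product of real-data
preprocessing (smooth maps within masks), not the preprocessing itself.

Default study conditions, chosen once as field-realistic values: baselines
MTsat 1.8 p.u., PD 80 p.u., R1 0.65 s^-1, R2\* 18 s^-1; noise sd 5% of
baseline per modality; cross-modality noise correlation 0.3; smoothing
FWHM 2 voxels; age slopes sized so the standardized effect over the cohort
age sd (21 y) is 0.4 in affected regions, with the field-typical signs
(MTsat and PD decline, R2\* rises, R1 weakly rises); modest gender, TIV
and scanner nuisance effects. `opposite_effects_phantom_spec()` isolates
the scenario that motivates the multivariate test: MTsat decreasing and
R2\* increasing in one region at equal amplitude, nothing in PD or R1.

What the phantom does *not* emulate: MR physics (no relaxometry or B1
bias), partial-volume mixing, anatomically realistic geometry, nonlinear
age trajectories, or site-dependent noise. Passing tests therefore
demonstrate the statistical machinery — estimator correctness, null
calibration, FWER validity, sensitivity ordering — not performance on real
acquisitions.

## Numerical and design notes

* OLS uses one QR decomposition of `X` shared across voxels; the voxelwise
  map evaluates `det(E)` and `det(E + H)` through vectorized small-matrix
  determinants, so results are independent of voxel traversal order
  (tested).
* The permutation loop never materializes permuted data: every needed
  projection of a permuted residual matrix equals a projection by a
  permuted small basis, reducing each permutation to a few thin-matrix
  products. The fast path is verified against a brute-force refit to
  1e-8.
* Zero residual variance (possible only on noiseless synthetic input)
  yields `p = 0` with a warning in the univariate map, and an error
  pointing at mask hygiene in the multivariate test (singular error SSCP).
* Degenerate designs (constant regressor, > 2 category levels under the
  single-column coding) are rejected with explicit errors. Gender and
  scanner are coded 0/1 then mean-centred; F-tests are invariant to affine
  recoding of a single column (tested), so the uncentred convention would
  give identical inference.
* Problem sizes used in the shipped validation studies: calibration of the
  Wilks null on 5,000 simulated voxels at n = 60; FWER validity on 200
  null phantoms (16^3 grid, n = 40, 500 permutations); sensitivity
  ordering on 50 phantoms at n = 100; slope recovery at n = 200 on an
  unsmoothed phantom. Recovery uses an unsmoothed phantom deliberately:
  smoothing is a spatial mixing operator that attenuates signal at region
  boundaries by construction, so it would bias any region-averaged slope
  estimate irrespective of the estimator.

## Limitations

Only Wilks' lambda is offered (no Pillai, Hotelling-Lawley or Roy
statistics), main-effects designs only (no interactions, no nonlinear age
terms), no cluster-extent or FDR inference, and no kappa confidence
intervals. The pipeline accepts any co-registered NIfTI stacks with a
covariate TSV, but spatial preprocessing (segmentation, normalization,
tissue-weighted smoothing) is out of scope and must happen upstream.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- default_config(seed = 1, output_dir = "demo_out")
run_pipeline("all", cfg)
```

This simulates a 40-subject 16^3 phantom, standardizes it, fits the four
univariate maps and the multivariate map, thresholds them, compares them
(union, overlap partition, Cohen's kappa), runs the ROI table and the
split-half cross-validation, and leaves every artifact with a manifest and
provenance JSON under `demo_out/`. The same stages are scriptable from a
shell through `inst/scripts/voxmanova.R`.
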