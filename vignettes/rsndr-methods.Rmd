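---
title: "Group-ICA dual regression with inter-component permutation inference: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-ICA dual regression with inter-component permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

Resting-state fMRI group studies of the kind this package supports ask
whether the intrinsic connectivity networks of two groups — here patients and
controls — differ in amplitude or spatial extent, after accounting for the
anatomical (gray-matter) differences that often accompany disease. The
pipeline has five stages, each a module of the package:

1. **Group spatial ICA** (`run_group_ica()`): per-subject variance
   normalization, temporal concatenation across subjects, reduction to a
   chosen model order by economy SVD, then fixed-point spatial ICA. Component
   maps are z-scored over the mask and sign-flipped to positive skewness.
   Running the decomposition on the control group only (the default in the
   drivers) keeps the template free of disease-related alterations.
2. **Mixture-model thresholding** (`fit_mixture_threshold()`): a
   three-component EM fit — Gaussian null plus positive and mirrored negative
   gamma — to each map's intensity histogram; a voxel survives when its local
   false-discovery rate (posterior null probability) is below 0.5.
3. **Dual regression** (`dual_regression()`): stage A regresses each time
   point's voxel pattern on all template maps simultaneously, giving a
   subject time-course matrix; stage B regresses each voxel's time series on
   those time courses, giving subject-specific spatial beta maps. The
   `des_norm` switch scales stage-A columns to unit standard deviation so
   that betas carry amplitude as well as shape information; without it betas
   reflect shape only.
4. **Inference** (`yconcat()`, `permutation_test()`): per-component
   subject-by-voxel blocks are concatenated into one joint dataset. The group
   difference is a pooled-variance two-sample t per voxel (or the group
   coefficient's t with the voxel-wise GM covariate), enhanced by TFCE, and
   referred to a single null distribution of the **maximum** enhanced
   statistic across *all* components and voxels under label permutation —
   family-wise error control across components and voxels jointly. A
   single-block variant (`per_map_test()`) gives the voxel-level-only
   correction for comparison.
5. **Summaries** (`difference_map_table()`, `atrophy_adjacency()`):
   per-component voxel counts, peak locations and t statistics of the
   significant masks, and the distance profile of significant voxels around
   an atrophy region.

# The synthetic cohort model

No patient data ships with the package; cohorts are generated
(`simulate_cohort()`) with the statistical structure the analysis assumes:

* Voxel signal is `sum_k map_k(v) * c_k(t) + noise(v, t)`. Network maps are
  unit-peak Gaussian blobs placed with a minimum pairwise separation; time
  courses are white noise band-limited below 0.08 Hz by frequency-domain
  masking and then rescaled to an exact target standard deviation; noise is
  i.i.d. Gaussian.
* Defaults mirror a realistic acquisition: TR 1.8 s, 285 time points,
  19 + 19 subjects, 4 mm voxels. Tests and drivers scale the cohort down
  (smaller grids, T = 40–150, 6–10 subjects per group) — choices listed with
  each experiment below.
* Patient-only effects are declared per network (`effect_spec()`): an
  amplitude ratio on the time-course standard deviation, an optional extra
  spatial blob, and an optional atrophy sphere with two separable knobs —
  `gm_reduction` multiplies the GM map by `1 - r`, `bold_attenuation`
  multiplies the network weights by `1 - a` inside the sphere. Real atrophy
  conflates the two; keeping them separable lets the confound-adjustment
  behaviour be probed with either alone.
* GM maps are a smooth baseline (0.7 inside a brain ellipsoid) plus
  per-subject Gaussian jitter (sd 0.02), minus atrophy.
* Determinism: per-subject seeds derive from the cohort seed; identical
  configuration + seed regenerates a cohort bit-identically.

What the generator deliberately does **not** model: hemodynamics,
physiological noise, motion, scanner drift, spatial autocorrelation of the
noise, and between-subject variability in network amplitude (time courses
are rescaled to the exact requested standard deviation). Passing tests
therefore demonstrate correctness of the estimators and error control under
the stated model, not robustness to every property of real data.

# Numerical and design choices

**ICA.** Dimensionality reduction is an economy SVD; model order is
user-set. The contrast is tanh with symmetric decorrelation, tolerance 1e-6,
at most 1000 iterations, deterministic seeding with up to 5 deterministic
restarts. Two practical behaviours are worth knowing. First, requesting an
order far above the data's signal rank leaves whitened directions that are
almost exactly Gaussian, on which the fixed-point iteration has no stable
fixed point — non-convergence is then reported as an error rather than
silently returning noise components. Second, per-voxel variance
normalization rescales every voxel to unit variance, so a recovered map is a
*saturated* version of the planted blob (`map/sqrt(map^2 + sigma^2)` at
amplitude 1); recovery correlation against the planted map is therefore
highest at moderate noise, and the recovery experiment uses `noise_std 0.7`,
12 control subjects and the full 285 time points, where matched correlations
exceed 0.95 at orders 5 and 7 for 5 planted networks.

**Mixture threshold.** Gamma offsets are fixed at the initial robust
null-mean estimate (median; scale from the IQR) so the EM support never
moves and the log-likelihood is provably non-decreasing; gamma shapes are
constrained to at least 1 so the activation densities stay bounded at the
offset instead of spiking there and swallowing null mass on pure-null maps.
Weighted gamma M-steps use Newton iterations on the shape. A component
weight collapsing to zero is reported, not an error.

**Dual regression.** Template maps are demeaned over the mask, voxel time
series over time, stage-B design columns likewise; `des_norm` scales to unit
standard deviation (not unit norm). Least squares go through QR with a rank
check; collinear templates are refused naming the worst pair. One inherent
property worth stating: stage-A estimation noise attenuates stage-B betas by
`amp^2/(amp^2 + sigma_e^2)`, a factor that depends on the true amplitude, so
even without variance normalization a large amplitude difference leaks
faintly into the betas at high sensor noise. The "des_norm off implies
amplitude-invariant betas" contract is exact in the low-noise limit and is
tested there.

**TFCE.** Height exponent 2, extent exponent 0.5, 100 integration steps of
`max(stat)/100`, 26-connectivity — the cited technique's standard values.
Integration uses the midpoint rule, which reproduces the isolated-voxel
closed form (`h^3/3`) to 0.002% and keeps the 100-step map within 1% of a
10-times-finer integration in aggregate; the per-voxel quantization floor of
a 100-step grid is about 1/200 of the map maximum. The implementation is an
incremental union-find over descending thresholds (compiled); tests verify
exact agreement with an independent per-threshold component-labelling oracle
at equal step counts.

**Joint inference.** Blocks are joined statistically, not geometrically: a
literal stacking of volumes could let clusters bridge adjacent components
across the seam, so TFCE runs per block and only the null *maximum* is shared.
Contrasts are one-sided per direction. Corrected p uses the add-one
estimator, so p is never 0 and never below `1/(n_perm + 1)`; significance is
strict inequality at alpha. When the number of distinct label arrangements
is at most `n_perm` (and no covariate is present), the null is enumerated
exhaustively instead of sampled. The voxel-wise GM covariate is handled by
Freedman–Lane: residualize on the nuisance per voxel, permute residuals,
refit the full model. Zero-variance voxels get t = 0 and can never reach
significance. GM covariate maps are smoothed with a Gaussian of sigma 3 mm
(FWHM = 2.355 sigma) before use.

**Summaries.** The t standard deviation within a significant mask is the
population form (divide by n), so single-voxel regions report 0. Peak
locations are 0-based voxel indices; distances in the adjacency report are
Euclidean in voxel units (mm via the affine is available but not the
default, keeping the report grid-deterministic).

**Geometry.** Everything requires identical grids and affines and refuses to
resample; registration is out of scope. Masks are stored as 8-bit 0/1
NIfTI-1, volumes as float64 so round-trips are bit-exact.

# Calibration experiments and problem sizes

The validation experiments (`fwer_null_experiment()`, `power_experiment()`,
`confound_experiment()`) run the same code path as a real analysis. Sizes
were chosen once as the package's desk-scale study conditions:

* **Null error control**: 200 independent global-null cohorts on a
  24 x 24 x 16 grid with a ~500-voxel ellipsoid mask, 6 networks, 8 + 8
  subjects, T = 100 (the permutation test's validity does not depend on the
  series length), dual regression against the truth atlas, 250 permutations.
  The joint and the single-map tests share each cohort. Both empirical
  family-wise error rates are compared to the nominal 0.05 through their
  lower one-sided 95% binomial bound.
* **Power**: amplitude ratio 2 on one network, 10 + 10 subjects, 50
  replicates; detection means a significant voxel of that network's block
  overlapping the truth blob (map weight at least 0.5) at the corrected
  level.
* **Confound adjustment**: the only planted group difference is an atrophy
  sphere (GM reduction and BOLD attenuation 0.4) on one network; 15
  replicates with and without the voxel-wise GM covariate, against 15
  matched null replicates. Observed behaviour: roughly a hundred significant
  voxels per cohort without the covariate, about two with it, zero in the
  null — the covariate removes ~98% of the confounded signal. The residual
  few voxels trace to the near-collinearity of the group indicator with the
  GM covariate inside the atrophy sphere (within-group GM variation is only
  the 0.02 jitter), which inflates the group coefficient's variance faster
  than the Freedman–Lane null captures; the test therefore asserts return to
  within a few voxels of the matched null level rather than exact equality.

# Known limitations

* The z-scoring of component maps is plain demean/unit-variance over the
  mask; reference tools normalize by a residual-noise standard deviation
  estimate, which shifts mixture-model thresholds somewhat.
* Model-order estimation is out of scope; the order is user-set, and orders
  far above the signal rank fail loudly (see above).
* The permutation engine covers two-group designs with an optional
  voxel-wise nuisance covariate; paired designs, continuous covariates of
  interest, and cluster-mass thresholding variants are not implemented.
* Whether a template/design intercept should be explicit rather than handled
  by demeaning is testably nil for balanced inputs; demeaning was chosen.
* Table-style peak coordinates are voxel indices of the analysis grid, not
  mm coordinates of a standard space.
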