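---
title: "Methods: radiomic signatures for IDH phenotype and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic signatures for IDH phenotype and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lggradiomics)
```

## The analysis

Lower-grade gliomas (WHO grade II–III) split into two clinically distinct
phenotypes by *IDH* (isocitrate dehydrogenase) mutation status: mutant
tumors have markedly better prognosis than wild-type tumors. `lggradiomics`
implements a complete radiomic pipeline that works from a T2-weighted MRI
volume and a manually traced tumor mask:

1. **Extraction** — a fixed 431-descriptor feature vector per tumor:
   14 first-order intensity statistics, 8 three-dimensional shape
   descriptors, 22 gray-level co-occurrence (GLCM) and 11 gray-level
   run-length (GLRLM) texture descriptors, and the same 47
   intensity/texture descriptors recomputed on each of the 8 sub-bands of a
   single-level stationary 3D wavelet decomposition (8 × 47 = 376).
2. **Differential selection** — a two-class SAM (significance analysis of
   microarrays) screen with a permutation null and Benjamini–Hochberg FDR,
   identifying features expressed differentially between *IDH* mutant and
   wild-type tumors.
3. **Classification** — ridge-stabilized logistic regression on the
   selected features with backward elimination by Wald p-value, evaluated
   by ROC AUC, with validation cohorts scored by the frozen training model.
4. **Prognosis** — univariate Cox screening of the *IDH*-specific features,
   a risk score defined as the β-weighted sum of the retained features, a
   log-rank-optimal cutoff learned on training data, and Kaplan–Meier
   stratification with multivariate Cox adjustment.
5. **Radiogenomics** — Pearson correlation of features (or the risk score)
   against gene expression, top-k ranked gene lists, and a local
   hypergeometric gene-set enrichment against a user-supplied GMT
   annotation.

Because no patient images are distributed with the package, a first-class
synthetic module generates tumor phantoms and full cohorts with *planted*
class, survival, and expression effects. Every downstream stage is
validated by recovering those planted effects.

## Preprocessing

Masked intensities are z-scored per tumor — `(v - mean) / sd` over masked
voxels only, never across a cohort — using the sample standard deviation
(n − 1). The convention matters little at tumor sizes of thousands of
voxels but is pinned for reproducibility. Constant regions are rejected as
errors rather than silently propagated.

Texture matrices require discrete gray levels. We quantize *after*
z-scoring into `quantization_levels` (default **Ng = 32**) equal-width bins
spanning the observed range, the maximum mapping to level Ng. Equal-width
min/max binning makes the full texture block invariant to positive affine
rescalings of the raw image, which we verify by property test. Ng = 32 is
standard radiomics practice; it is exposed in `analysis_config()` and every
texture test pins it explicitly.

## Feature definitions and numerical choices

* **First order (14)** — energy, entropy, kurtosis, maximum, mean, mean
  absolute deviation, median, minimum, range, root mean square, skewness,
  standard deviation, uniformity, variance. Entropy and uniformity use an
  equal-width histogram with the configured bin count; all entropies in
  the package are base-2 (bits) with 0·log 0 ≡ 0. Degenerate moments of
  constant data (skewness, kurtosis) return 0 by convention.
* **Shape (8)** — volume (voxel count × voxel volume), surface area,
  surface-to-volume ratio, sphericity π^(1/3)(6V)^(2/3)/A, compactness 1
  and 2, spherical disproportion, and maximum 3D diameter (largest pairwise
  distance between surface voxel centers, in mm). Surface area comes from a
  triangulated isosurface built by marching tetrahedra at iso-level 0.5 on
  a lightly smoothed ([1,2,1]/4 separable) indicator field, so vertices
  interpolate between voxel centers; on a discretized radius-10 sphere this
  reproduces the analytic area within ~1%. One-voxel-thin masks fall back
  to the raw indicator so the mesh never vanishes. Shape features are the
  only group that uses physical spacing.
* **GLCM (22)** — distance-1 co-occurrences over the 13 unique 3D lattice
  directions, pooled into a single matrix before symmetrization and
  normalization (pooling is chosen over per-direction averaging for
  determinism and simplicity and is pinned in tests). Offsets act on the
  voxel lattice with no resampling: the analysis runs in native,
  anisotropic space, and spacing informs shape features only. Degenerate
  statistics (correlation under zero marginal variance, IMC1 under zero
  marginal entropy) return 0.
* **GLRLM (11)** — maximal same-level runs along the same 13 directions,
  aggregated; run percentage is n_runs / (n_voxels × 13).
* **Wavelet (376)** — the tumor bounding box of the z-scored volume is
  decomposed by a single-level *stationary* (undecimated, hence
  shift-invariant) separable 3D wavelet transform with periodic boundary.
  Default family **coif1**; `db2` and `haar` are also available. Sub-band
  letters follow (x, y, z) axis order — HLL is high-pass along x — and this
  naming is frozen. On each sub-band the 47 intensity/texture descriptors
  are recomputed on the masked voxels after the same quantization rule.
  Applying the transform to the z-scored (not raw) volume is what preserves
  the affine-invariance guarantee of the whole 431-vector. For orthonormal
  families the 8 sub-band energies sum to exactly 8× the input energy,
  which the tests exploit as a Parseval check.

## Statistical stages

**SAM.** The moderated statistic is d = (mean₂ − mean₁)/(s + s₀) with s the
pooled two-sample standard error and s₀ the median of the per-item s (the
common "median" fudge-factor rule). The null is built from seeded label
permutations *pooled across items*, giving usable p-value resolution at
small n; p-values are then BH-adjusted. We deliberately pair permutation
p-values with BH rather than classic SAM q-values, and we apply the
20% fold-change criterion only to gene selection, not radiomic features,
where the criterion is a ratio of group means (linear scale; a `log_base`
argument converts log-scale expression differences). Null simulations over
20 seeds confirm near-zero selections at FDR 0.05, and power exceeds 0.9
for 2-sd shifts at n = 30/group.

**Classification.** The paper-scale setting — more features than samples
with perfect training separation — makes unpenalized maximum likelihood
diverge, so fits carry a small ridge penalty (default λ = 1e−4) on the
slopes only; this stabilizes the Wald ordering used by backward elimination
without materially changing discrimination. Backward elimination drops the
largest-Wald-p feature each round and records training AUC at every size;
the chosen model is the smallest attaining the maximum AUC (tie → fewer
features), and the full trace is saved so alternative stopping rules can be
replayed. An intercept is always included. Validation data are standardized
with the frozen training center/scale, never their own. AUC uses the
rank-based Mann–Whitney formulation with ties counted ½, verified against
exhaustive pair counting.

**Prognosis.** Cox fits use Efron tie handling (day-resolution survival
ties heavily) via the `survival` package's Newton–Raphson partial
likelihood; reported HRs satisfy HR ≡ exp(β) and HR ≡ √(CI_lower·CI_upper)
exactly, an identity we also enforce as a test on outputs. Patients
surviving fewer than `min_survival_days` (default 30) are excluded from
*signature construction only*, not from KM plotting of predefined groups.
The risk score is the exact β-weighted sum of the same z-scored feature
values used by the classifier. The cutoff scan evaluates midpoints of
adjacent sorted unique scores, requires at least 10% of samples per side
(unconstrained scans are degenerate at the extremes), minimizes the
log-rank p, breaks ties toward the lower cutoff, and is frozen before being
applied to any other cohort. The scan optimizes a minimum p-value and is
therefore optimistic as a test; we report it as a stratification device,
not an inferential p. The multivariate adjustment uses sex, age, grade,
IDH status and risk group.

**Radiogenomics.** Pearson r with a two-sided t-test (n − 2 df) per
(feature, gene) pair; significance requires |r| > 0.4 *and* p < 0.05.
Zero-variance genes are excluded with a logged reason rather than assigned
r = 0, avoiding silent significance distortions. Ranked lists filter by
significance first, then truncate to k = 200 (both counts are available in
the returned table). Enrichment is a one-sided hypergeometric tail with BH
adjustment against a user-supplied GMT annotation — a deliberately local,
download-free replacement for web-based GO services.

## The synthetic-data generator

Phantoms are analytic shapes discretized on the voxel grid (a voxel is
foreground when its center satisfies the shape inequality). Surface
irregularity is a radial perturbation of a sphere by a smooth random field
on the direction sphere (random low-order spherical harmonics), whose
amplitude maps monotonically to surface-to-volume ratio — verified
empirically in the test suite. Texture is Gaussian noise, optionally
blurred (per-class smoothness) and rescaled to unit foreground sd.

Cohorts draw two latent variables per sample: z1 modulates irregularity,
z2 the mean intensity; the class effect is an intensity shift δ on the z2
axis in units of the within-class sd of the per-sample mean, so δ = 2
produces the "2-sd shift" condition used in the recovery tests (default
cohort conditions: 20 + 20 samples, radius-7-voxel spheres, smoothness
0.8/1.6 voxels, irregularity 0.05/0.15 — sizes chosen so the full suite
exercises real extraction while remaining desk-scale). Survival uses an
exponential baseline h(t) = λ₀·exp(Σβ_k z_k) (default λ₀ = 1/1000 per day,
β = 0.7 on z1, 20% censoring), giving closed-form sanity checks — doubling
exp(risk) halves median survival — and censoring is independent uniform
over a horizon solved numerically to hit the target censored fraction.
Expression planting regresses each planted gene on the *extracted* (or
supplied) feature values: gene = ρ·z(feature) + √(1−ρ²)·noise, so the
Pearson screen has a well-defined target ρ.

What the generator does **not** emulate: MRI physics (bias fields, Rician
noise, partial-volume effects), multi-sequence acquisition, registration or
segmentation error, and cohort-level scanner heterogeneity. Passing
recovery tests therefore demonstrates the correctness and statistical
calibration of the pipeline, not clinical performance on real images.

## Design decisions made where the field is genuinely open

* Whether to resample anisotropic voxels (0.6 × 0.6 × 5.0 mm T2 volumes)
  before texture computation is unstated in much of the literature; we
  operate in native space and expose spacing to shape features only.
* Quantization order (z-score first, then bin) and Ng = 32 are recorded in
  the configuration; both are unstated in the motivating analysis.
* The elimination stopping rule "best predictive effect" is operationalized
  as maximum training AUC with fewest features.
* Risk-score features use the same z-scored values as the classifier.
* The "top 200" gene lists are taken after the significance filter.

## Known limitations

* The cutoff scan's minimum log-rank p is optimistic (no correction for
  the scan); downstream survival comparisons on the same data inherit it.
* The feature catalog follows the published 431-descriptor definitions but
  is not IBSI-certified; minor normalization differences from other
  radiomics codebases are possible and are documented per feature group
  above.
* Permutation p-values are pooled across items, which assumes approximate
  exchangeability of item null distributions after the s₀ moderation.

## Reproducibility

All randomness flows through explicit seeds: generators take a seed in
their spec, `sam_select()` seeds its permutations, and `run_pipeline()` is
a pure function of (inputs, config) including `config$seed`. Problem sizes
used by the test and acceptance runs (64³ phantom for the catalog check,
40-sample image cohorts, n = 1000 survival simulations, n = 48 correlation
screens, 10–20 seed replicates) were chosen as the smallest sizes at which
the planted effects are comfortably identifiable.
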