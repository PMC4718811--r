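---
title: "Metabolic connectivity maturation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic connectivity maturation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metconn)
```

## The measurement model

FDG uptake integrated over tens of minutes is a proxy for cumulative
regional energy consumption. Unlike fMRI time series, a static PET scan
gives one number per region per animal, so connectivity cannot be a
within-subject temporal correlation: it is the Pearson correlation of
regional uptake **across the subjects of a group**. Two regions whose
metabolic levels rise and fall together over animals are taken to be
metabolically coupled. The subjects are the samples; with n = 28–30
animals per age group, a single correlation carries a standard error of
roughly `1/sqrt(n-3)` ≈ 0.2 on the Fisher-z scale, which drives every
power consideration below.

All volumes are assumed co-registered to a common stereotaxic frame.
Nonlinear registration to a template is deliberately out of scope: the
synthetic generator produces pre-aligned volumes, and users of real data
must supply their own registration.

## Preprocessing

Three steps, in order:

1. **Voxel scaling** (`scale_voxels`, factor 10): rodent volumes are
   conventionally inflated ×10 so human-calibrated kernel sizes and
   cluster extents apply. All coordinates in the package — voxel spacing
   (3.875 × 3.875 × 7.75 mm), VOI centres, the 8 mm sphere radius, the
   12 mm smoothing kernel — live in this scaled frame.
2. **Gaussian smoothing** (`gaussian_smooth`, default FWHM 12 mm):
   separable convolution with per-axis sigma `fwhm / sqrt(8 ln 2) /
   spacing`, so anisotropic grids are smoothed isotropically in mm.
   Boundary handling is zero-padding, the common neuroimaging convention;
   consequently total intensity is conserved only away from the grid
   boundary, which is irrelevant here because the brain mask keeps well
   inside.
3. **Global-uptake normalization** (`global_normalize`): division by the
   arithmetic mean over the binary brain mask, making the in-mask mean
   exactly 1. We chose mean-based division (rather than proportional
   scaling to an arbitrary grand mean) because only the *relative*
   scale matters downstream and the unit in-mask mean makes uptake
   directly interpretable as a fraction of global activity. The operation
   is idempotent and makes every later statistic invariant to global
   intensity rescaling — an invariance the test suite checks end-to-end.

Smoothing precedes normalization, matching the usual pipeline order for
covariance analysis.

## Voxelwise contrasts

Age contrasts are paired t tests on within-subject differences (the design
is longitudinal), with two-sided p-values on n − 1 degrees of freedom.
When groups differ in size (animals lost between time points), the paired
analysis restricts to the subject-ID intersection; an unpaired Welch
fallback is available by flag. Zero-variance voxels get t = 0, p = 1
rather than infinities — on synthetic data exactly identical voxels can
occur.

Multiplicity is handled by Benjamini–Hochberg FDR at q = 0.05 over in-mask
voxels only (the out-of-mask voxels carry no hypotheses), followed by a
100-voxel cluster extent filter under 18-connectivity (faces + edges), the
convention of mainstream SPM-style pipelines; both the connectivity code
and the extent are configurable. Positive and negative effects are
clustered separately so a reported cluster never mixes directions.

## Group spatial ICA

The pooled subjects × in-mask-voxels matrix is centred per voxel, reduced
by PCA on the subject covariance (cheap: the small dimension is the
subject count), and unmixed with infomax — natural-gradient ascent of
output entropy through a logistic nonlinearity, which for super-Gaussian
(spatially sparse) sources minimizes the mutual information between
component maps. Implementation specifics, since "infomax" alone
underdetermines the algorithm: full-batch natural-gradient updates,
random orthonormal initialization from a mandatory seed, learning rate
0.05 halved on divergence, convergence when the relative weight update
drops below 1e-6, at most 500 iterations; non-convergence is flagged in
the result, never silent. Components are sign-aligned to positive
skewness (peaks read as activations), z-scored over in-mask voxels, and
displayed at z > 1.5.

The model order is estimated by minimum description length on the PCA
eigenspectrum: the code-length balance between the sphericity of the
trailing (noise) eigenvalues and a parameter-count penalty. Two details
matter in practice. Per-voxel centring removes one rank, so the null
eigenvalue must be excluded before the scan — otherwise the criterion
runs away to the maximum order. And spatially smooth voxels are not
independent samples, so the effective sample count is exposed as
`sample_correction` (default 1); with ~10^4 voxels the estimate is robust
for well-separated sources at SNR ≥ 10, which the tests verify by
simulation. The estimator reports the full eigenspectrum alongside the
estimate rather than asserting a single "true" dimensionality.

## VOI connectivity and permutation inference

Eight spherical VOIs (radius 8 mm, scaled frame) sit at stereotaxic
(ML, DV, AP) centres covering the limbic/anterior-DMN, posterior-DMN,
motor and somatosensory components; grid mapping is x = ML, y = AP,
z = DV with DV stored as positive depth (the sign convention of the DV
axis is otherwise ambiguous, and any consistent choice leaves in-sphere
distances unchanged). A voxel belongs to a sphere when its centre lies
within the radius in mm, respecting anisotropic spacing.

Group differences per edge use the statistic Δz = z_B − z_A on Fisher's
scale. The null is built by pooling the subjects of both groups and
reassigning labels at random (preserving group sizes) 10,000 times —
pooled relabelling rather than within-pair swapping, because the
comparison treats the two ages as exchangeable populations. P-values use
the add-one estimator `(1 + #{|Δz*| ≥ |Δz|}) / (n_perm + 1)`, which never
returns zero, and are FDR-corrected over the 28 edges of one comparison
(not pooled across comparisons — each age contrast is its own family).
Tests are two-sided by default with one-sided modes by flag; edges with
negative observed r still enter the test, since exclusion of negative
links is specific to the strength definition below. Correlations of
exactly ±1 (possible only on degenerate input) are clamped to
`atanh(1 - 1e-7)` with a warning rather than propagating infinities.

## Energy efficiency

Node strength is the sum of positive incident correlations,
S_i = Σ_{j≠i} max(r_ij, 0); energy efficiency is E_i = S_i / u_i with u_i
the group-mean normalized uptake of region i — connections sustained per
unit metabolic cost. Uptake is averaged at the group level because
efficiency is here a group-level network quantity; a per-subject variant
would require per-subject networks, which a single static scan cannot
give. The permutation test recomputes *both* S and u for every
pseudo-group (holding u fixed would understate the null variance), and
significance is Bonferroni over the 8 regions at family α = 0.05
(per-test 0.00625) — deliberately stricter than the edgewise FDR, since
only eight hypotheses are in play.

## The synthetic cohort generator

`generate_cohort()` builds, per subject: a fixed smooth ellipsoidal
background dome (so normalization has real work to do), plus
subject-specific scalar loadings on the eight spherical VOI supports drawn
from a multivariate normal with group-specific means and covariance, plus
i.i.d. Gaussian voxel noise, then Gaussian smoothing for intrinsic
smoothness. A single seeded stream drives the whole cohort in a fixed
order, so identical configs are bit-identical.

Defaults encode the study design: groups of 30/30/28; anterior regional
means rising and posterior/limbic means falling with age; loading SD 0.08
against a background of ~1; voxel noise SD 0.02; intrinsic smoothness
4 mm FWHM. The across-subject correlation defaults use a three-parameter
structure — homologous left–right pairs at 0.5, hippocampal edges fixed
at 0.2 across ages, and all cortical anterior–posterior edges sharing a
single maturation dial r_ap = 0.15 / 0.45 / 0.65 at 5 / 10 / 15 weeks.
No published inter-subject variance exists for this design, so the noise
scale is a free parameter chosen once such that planted effects at the
published sample sizes are recoverable; with ~25 voxels per sphere the
noise contribution to a VOI mean (SD 0.02/√25 = 0.004) is negligible
against loading SD 0.08, so extracted correlations track planted ones.

Ground truth records the planted correlation matrices (unit diagonal),
means, component maps, the background mean per sphere, and the
deterministic 8×8 *gain matrix* of smoothing: each planted loading is
attenuated within its own sphere (≈ 0.91 at the default FWHM) and bleeds
marginally into close neighbours (≲ 0.003), so extracted means equal
`background + gain %*% planted_means` exactly in expectation. Correlations
are essentially unaffected because the gain factors out of each column.

What the generator does **not** emulate: PET physics (attenuation,
scatter, reconstruction artifacts), anatomy beyond an ellipsoid,
registration error, anesthesia effects, or heavy-tailed biological
variability. Passing tests therefore show the *analysis machinery* is
correct and calibrated — not that real rat data would yield any
particular biology.

## Numerical choices and degenerate inputs

- Smoothing kernels truncate at 4 sigma and renormalize to unit mass.
- MVN draws use an eigendecomposition square root, valid for singular
  (PSD) covariances; non-PSD input is rejected with the offending
  eigenvalue.
- Cluster labelling is breadth-first flood fill; label order is by
  decreasing size, and sizes are invariant to voxel visiting order.
- `bh_fdr` returns both step-up rejections and monotone BH q-values
  (q ≥ p always).
- Empty p-vector in, empty rejection set out — not an error.
- Degenerate inputs rejected with named diagnostics: zero-variance VOI
  columns, non-positive uptake (efficiency undefined), empty spheres,
  centres outside the grid, groups below the minimum size.

## Problem sizes used in validation

The shipped tests and the acceptance script run on a compact stereotaxic
frame — the standard VOI table at half scale on a 20 × 24 × 6 grid with
the study's voxel spacing — which keeps sphere geometry and all statistics
honest while making hundreds of simulated cohorts cheap. In the test
suite, calibration uses 500 null cohorts (15 + 15 subjects, 1,000
permutations each); power uses 200 cohorts at the published 30/30 sizes;
efficiency direction recovery uses 100 cohorts at 30/28; ICA recovery
uses 10 seeded 40-subject datasets with 4 planted components. The
acceptance script re-estimates the same rates with lighter replicate
counts (150 / 100 / 60). These sizes were chosen as the smallest at which
the binomial error of each estimated rate is well inside the margins
being checked.

## Known limitations

- Across-subject correlation conflates within-animal coupling with any
  shared between-animal covariate (weight, anesthesia depth); the method
  cannot distinguish them, in synthetic or real data.
- The paired voxelwise t assumes exchangeable scan pairs; no longitudinal
  mixed modelling is attempted.
- Infomax with a logistic score targets super-Gaussian sources only;
  sub-Gaussian components would need an extended-infomax score switch,
  not implemented.
- The permutation schemes treat subjects as exchangeable under the null,
  which ignores the longitudinal pairing structure; a within-pair
  permutation variant would be more conservative and is not implemented.
- Efficiency inherits every caveat of the strength definition: negative
  correlations are discarded, and r-based weights are not partial
  correlations, so indirect coupling inflates strength.
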