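# metconn

Metabolic connectivity maturation analysis for multi-subject FDG-PET
cohorts, with a fully synthetic validation harness.

## What this is for

Resting glucose metabolism, imaged with ^18^F-FDG PET, covaries across
subjects between functionally coupled brain regions. Correlating regional
uptake *across the subjects of a group* ("metabolic connectivity") reveals
large-scale networks — including the rodent default mode network — and how
they reorganize during maturation. `metconn` implements the full analysis
chain for cohorts of co-registered 3D volumes from a longitudinal rodent
design (three age groups of 30/30/28 animals):

1. **Preprocessing** — voxel-grid scaling (×10 rodent convention), separable
   Gaussian smoothing (default 12 mm FWHM in the scaled frame), and
   global-uptake normalization so each scan's in-brain mean is 1.
2. **Voxelwise contrasts** — paired t maps between age groups,
   Benjamini–Hochberg FDR at q = 0.05, and a 100-voxel cluster extent
   filter with 6/18/26-connectivity labelling.
3. **Group spatial ICA** — MDL model-order estimation on the subject
   covariance eigenspectrum, then infomax unmixing (natural gradient,
   logistic nonlinearity) of the pooled subjects × voxels matrix;
   z-scored maps displayed at z > 1.5.
4. **VOI connectivity** — spherical volumes of interest (radius 8 mm,
   scaled frame) at eight stereotaxic coordinates (bilateral hippocampus,
   medial prefrontal, retrosplenial, bilateral motor and somatosensory
   cortex); per-group 8×8 Pearson/Fisher-z matrices over the 28 unique
   edges; group differences tested by permuting pooled group labels
   10,000 times with FDR control over edges.
5. **Energy efficiency** — per-region connectivity strength
   S_i = Σ_{j≠i} max(r_ij, 0) divided by normalized regional uptake u_i,
   E_i = S_i / u_i; group differences by the same permutation scheme with
   Bonferroni correction over the 8 regions (per-test threshold 0.00625).

Because real scans of this design are rarely shareable, the package ships a
first-class synthetic cohort generator (`synthetic_config()`,
`generate_cohort()`) that plants group-specific regional means,
across-subject covariance between the VOI regions, spatial component maps,
voxel noise and smoothness — so every stage can be validated against known
ground truth.

## Core model

For regions i, j with per-subject mean uptake x_i, x_j within one group,
connectivity is the Pearson correlation r_ij across subjects, compared
between groups on the variance-stabilized scale z = atanh(r):

    Δz_ij = z_ij(group B) − z_ij(group A)

with significance from the permutation distribution of Δz under pooled
relabelling (add-one two-sided p), FDR-corrected over the 28 edges.
Efficiency contrasts use ΔE_i with strength and uptake recomputed per
pseudo-group, Bonferroni-corrected over regions.

## Worked example

```r
library(metconn)

cfg <- pipeline_config(
  synthetic = synthetic_config(group_sizes = c(`5wk` = 30, `10wk` = 30,
                                               `15wk` = 28), seed = 1),
  n_perm = 1000, n_components = 4, seed = 1)
rep <- run_pipeline(cfg)
rep
#> <pipeline_report> 88 volumes in 3 groups; stages: voxelwise, ica, connectivity, efficiency

rep$connectivity$comparisons[[3]]$comparison
#> [1] "15wk_vs_5wk"
head(subset(rep$connectivity$comparisons[[3]]$edges, significant,
            c(voi_i, voi_j, r_a, r_b, dz, p)), 3)
#>   voi_i voi_j        r_a       r_b        dz           p
#> 6  MedF   Rsp  0.1643237 0.6745261 0.6531745 0.008991009
#> 8  Hp_R Mot_L -0.1677148 0.3944978 0.5864301 0.012987013
#> 9  MedF Mot_L  0.1288315 0.7110666 0.7597865 0.003996004

eff <- rep$efficiency$comparisons[[3]]$vois
eff[eff$voi %in% c("MedF", "Rsp"),
    c("voi", "efficiency_a", "efficiency_b", "de", "p", "significant")]
#>    voi efficiency_a efficiency_b       de           p significant
#> 3 MedF    0.6614366     1.853062 1.191625 0.000999001        TRUE
#> 4  Rsp    0.8065957     3.737288 2.930692 0.000999001        TRUE
```

The default synthetic cohort plants the maturation signature the analysis
is designed to detect — anterior–posterior coupling rising from r ≈ 0.15
(5 wk) to r ≈ 0.65 (15 wk) with unchanged hippocampal edges — and the
edge tests recover it: `dz` is the Fisher-z increase and `p` the add-one
permutation p-value (FDR-significant rows shown). Energy efficiency of the
midline regions (medial prefrontal, retrosplenial) rises accordingly and
survives Bonferroni correction over the 8 regions.

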