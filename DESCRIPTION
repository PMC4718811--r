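Package: metconn
Title: Metabolic Connectivity Maturation Analysis for Multi-Subject PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study maturation of brain metabolic networks from
    cohorts of co-registered 3D FDG-PET volumes. Provides preprocessing
    (voxel scaling, Gaussian smoothing, global-uptake normalization),
    voxelwise paired contrasts with false-discovery-rate correction and a
    cluster extent filter, group spatial independent component analysis
    with an infomax unmixing algorithm and MDL model-order estimation,
    across-subject interregional correlation ("metabolic connectivity")
    between spherical volumes of interest with permutation inference on
    Fisher-z differences, and per-region energy-efficiency statistics
    (node strength per unit normalized uptake). Includes a synthetic
    cohort generator with planted regional means, planted across-subject
    covariance and planted spatial components so every analysis stage can
    be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
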