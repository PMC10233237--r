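Package: eigenbrains
Title: Latent Spatial Factors, Data-Driven Subtypes, and Z-Score Maps for
    Voxel-Wise Brain Imaging Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes subject-by-voxel brain image matrices (e.g. FDG-PET
    SUVR volumes) into latent spatial factors ("eigenbrains") via singular
    value decomposition, selects the number of components with a latent-root
    criterion or Horn's parallel analysis, relates per-subject factor scores
    to clinical and cognitive variables with standardized multivariable
    regression, derives data-driven patient subtypes by affinity propagation
    clustering on factor scores with silhouette-based distance-metric
    selection and exemplar agglomeration, and produces voxel-wise Z-score
    maps of patient groups or individuals against a control cohort. Includes
    a synthetic-cohort generator with known ground truth (smooth orthonormal
    spatial factors, cluster-structured loadings, planted regression
    coefficients) so the full pipeline is testable end to end, plus minimal
    NIfTI-1 input/output and a single-config pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
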