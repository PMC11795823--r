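Package: deformark
Title: Data-Driven Soft-Tissue Biomarker Discovery from 2D Deformation Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovers disease-discriminative soft-tissue regions from a
    cohort of 2D mid-sagittal grayscale images. Subjects are rigidly
    aligned on anatomical landmarks and non-rigidly registered to a
    PCA-selected reference subject with Thirion demons registration; every
    pixel's local neighborhood of deformation magnitudes is screened with a
    cross-validated linear support vector machine to build a per-pixel AUC
    map; supra-threshold regions are refined by dilation-to-plateau and
    per-pixel boundary sweeps, combined by exhaustive subset search, and
    evaluated on reserved test subjects with ROC analysis; class-specific
    deformation directions within the winning regions are characterized by
    principal components analysis. Includes a synthetic-cohort generator
    with known ground-truth displacement effects so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
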