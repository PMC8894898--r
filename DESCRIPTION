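Package: hippasym
Title: Hippocampal Shape Asymmetry Biomarkers from Binary Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative imaging-biomarker pipeline for hippocampal
    sclerosis. Reads binary hippocampus label maps (NIfTI), extracts 14
    mesh-based 3D shape features via marching cubes (volume, surface area,
    surface-to-volume ratio, sphericity, diameters, principal-axis
    metrics), computes inter-hemispheric asymmetry indices, fits normative
    volume models (eTIV and age corrected) and healthy-control asymmetry
    limits, classifies scans at 2/3 SD thresholds with discrimination
    metrics (sensitivity, specificity, F1, ROC/AUC), ranks features with a
    repeated patient-stratified cross-validated linear SVM, and quantifies
    test-retest robustness (MAPE, ICC(2,1)). Includes synthetic cohort and
    hippocampus-phantom generators so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    e1071,
    jsonlite,
    yaml,
    ggplot2,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
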