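Package: proteodyn
Title: Proteome-Based Drug-Response Prediction and Perturbation Dynamics
    for Breast Cancer Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for data-independent-acquisition (DIA)
    proteomic matrices of breast cancer cell line panels: matrix-level
    quality control (missing-rate filtering, replicate diagnostics, batch
    centering, replicate averaging), protein-complex subunit co-expression
    at protein and transcript levels, TNBC differential expression with
    Benjamini-Hochberg control, nested cross-validated elastic-net
    drug-response prediction from multi-omics layers with bootstrap
    coefficient averaging and one-standard-error top-k selection, and
    drug-perturbation time-course analysis (IC50-correlation screening,
    fuzzy c-means clustering, opposite-dynamics selection, pathway
    consistency, persistently dysregulated proteins). Includes a synthetic
    cohort and time-course generator with planted ground truth so every
    stage is testable without the original deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    cluster,
    stats,
    utils
Suggests:
    e1071,
    yaml,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
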