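Package: rgepdecon
Title: Cell-Type Deconvolution of Bulk Tumour Expression with
    Single-Cell Reference Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the immune, stromal and malignant cell composition of
    bulk gene expression profiles by linear deconvolution against reference
    gene expression profiles (RGEPs) derived from single-cell RNA-seq data.
    Provides the full workflow: TPM/log2 preprocessing with housekeeping-gene
    normalization, marker-driven two-stage single-cell classification (t-SNE,
    DBSCAN, AND/OR/NOT marker scoring, decision-tree labelling with an
    "unknown" posterior threshold), pseudobulk construction, five reference
    profile configurations of increasing tissue- and patient-specificity,
    four deconvolution solvers (nu-support-vector regression, pseudo-inverse,
    least squares with intercept, L2-regularized non-negative least squares)
    with unknown-fraction accounting, accuracy benchmarking with bootstrap
    uncertainty, and patient-specific tumour expression purification by
    weighted subtraction. A seeded synthetic single-cell cohort generator
    emulating multiple tissue sources supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    pracma,
    Rtsne,
    jsonlite,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    quadprog
Config/testthat/edition: 3
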