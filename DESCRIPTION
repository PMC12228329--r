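Package: markeropt
Title: Marker Gene Set Optimization for Cell Type Annotation in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based cell type annotation for single-cell and single-nucleus
    RNA-seq with specificity-weighted z-score enrichment scoring, a
    leave-one-cell-type-out cross-validated objective for scoring candidate
    marker gene sets, and Bayesian optimization of marker sets using a
    Gaussian-process surrogate over a gene-set similarity kernel, Expected
    Improvement acquisition, and an expectation-maximization proposal step.
    Includes a negative-binomial single-cell count simulator with planted
    marker structure, readers and writers for Matrix Market and delimited
    expression matrices and marker-set files, and a permutation test for
    shifts in cell type composition between conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
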