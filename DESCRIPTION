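Package: scaxis
Title: Cell-Type Correspondence and In Silico Staging for Gastruloid
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell RNA-seq of stem-cell-derived
    gastruloids patterned along the anteroposterior axis, together with the
    reference embryo atlases they are compared against. Implements cell- and
    gene-level quality-control filters, total-count log-normalization,
    highly-variable-gene selection, covariate regression and PCA embedding;
    a reciprocal non-negative least squares (NNLS) statistic that matches
    cell types between two datasets from their pseudobulk cluster profiles;
    k-nearest-neighbour in silico developmental staging and neighbourhood
    cell-type composition in a joint PC space; principal-axis gene
    correlation analysis, RT-qPCR delta-Ct normalization and line-of-origin
    composition summaries. A negative-binomial synthetic-data generator with
    planted cell types, stage gradients and doublets provides ground truth
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
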