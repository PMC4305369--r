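Package: stemsig
Title: Microarray Signature Analysis for Multi-Cell-Type Stem Cell Transcriptomics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for single-channel microarray signature
    analysis across multiple cell types: GenePix-style probe intensity input,
    normexp background correction, within-array lowess and between-array
    quantile normalization, empirical-Bayes moderated t-statistics with
    Benjamini-Hochberg correction and dual significance/fold-change calling,
    summed fold-change ("FC score") signature extraction for cell-type-specific,
    shared-stem and germ-cell gene sets, cross-platform "virtual array"
    integration with ANOVA ranking, PCA and hierarchical clustering, and
    comparative delta-delta-Ct qPCR quantification. Includes a synthetic-data
    generator that plants known signatures so every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
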