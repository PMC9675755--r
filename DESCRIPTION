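Package: enhancersens
Title: Classification of Nuclear-Receptor Target Enhancers by Mutation
    Sensitivity, Accessibility and Response-Element Strength
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide classification of
    PPARg-bound enhancers: HOMER-style peak calling against a local Poisson
    background, window quantification of ChIP-seq and nucleosome-free
    ATAC-seq signal, a self-contained negative-binomial Wald test with
    Benjamini-Hochberg correction, PPRE position-weight-matrix scanning
    with DR1 half-site dissection, enhancer taxonomy (activation,
    mutation-sensitivity groups, accessibility, chromatin remodeling, ROC
    evaluation of predictors), gene-level target definitions with
    resampling-normalized enhancer-vicinity enrichment, and closed-form
    CD-helicity and NMR secondary-chemical-shift utilities. Ships a
    synthetic-data generator that plants response elements, condition
    specific binding and linked gene expression with a truth table, so the
    full analysis can be exercised and validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
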