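Package: stressmodes
Title: Transcriptional Response Modes Under Combined Abiotic Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for RNA-seq experiments that combine two
    abiotic stresses (cold, drought) with their single-stress and control
    counterparts. Provides a minimal negative-binomial differential
    expression engine (median-of-ratios normalization, method-of-moments
    dispersion, Wald tests, Benjamini-Hochberg adjustment), classification
    of genes into predefined expression profiles and five transcriptional
    response modes (similar, independent, combinatorial, canceled,
    prioritized), three-set Venn decomposition with overlap statistics and
    cumulative fold-change contribution, candidate selection for genes with
    enhanced expression under combined stress, and a seeded
    negative-binomial simulator with planted response modes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    SummarizedExperiment,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
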