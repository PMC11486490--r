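Package: rteage
Title: Retrotransposon Expression, Methylation and Biological-Age Signatures in Blood Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies retrotransposon (RTE) class and family expression and DNA
    methylation from probe-based microarray data, read-level bulk RNA-seq and
    pseudo-bulk single-cell RNA-seq, by mapping probes or reads onto
    RepeatMasker repeat annotation. Scores samples against biological-age gene
    signatures with a rank-based single-sample statistic, computes per-sample
    gene-set variation enrichment scores, and provides the stratified
    correlation, Wilcoxon contrast and high-versus-low differential-enrichment
    analyses used in aging cohort studies. A seeded synthetic-cohort generator
    emits genome annotation, expression, methylation and single-cell fixtures
    with known planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
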