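Package: crossplat
Title: Cross-Platform Comparison of Microarray and RNA-Seq Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing gene expression measurements made on
    microarray and RNA-Seq platforms from the same samples. Implements
    detectability filtering and probe collapsing, cross-platform concordance
    statistics (overlap rates, Pearson/Spearman correlation, expression
    density comparison), an errors-in-variables (Deming) regression with
    replicate-based error-variance-ratio estimation and bootstrap tests for
    fixed and proportional bias, a paired-platform simulator that couples a
    two-component microarray error model (with its variance-stabilizing
    transformation) to negative-binomial read counts through shared quantiles
    with preset differentially expressed genes, an evaluation harness scoring
    differential-expression callers against simulation truth (sensitivity,
    empirical FDR, specificity, overlap matrices, fold-change sweeps), and
    delta-delta-Ct arithmetic for qRT-PCR validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
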