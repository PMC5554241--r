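Package: tallmir
Title: IsomiR-Resolved Small RNA-Seq Analysis of T-ALL Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies microRNA isoforms (isomiRs) from small RNA
    sequencing reads in miRNA precursor space, summarises isomiR diversity
    and dominant isoforms, applies background filtering and median-of-ratios
    normalisation, tests differential miRNA expression with a negative
    binomial Wald test, and derives subtype-specific miRNA signatures for
    T-cell acute lymphoblastic leukemia against normal thymocyte subsets,
    separating differentiation-arrest markers from oncomiR candidates. A
    synthetic-data module generates annotation, ground-truth counts and
    FASTQ reads with the statistical structure the analysis assumes, so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
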