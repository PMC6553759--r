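Package: rrbsdmr
Title: Sliding-Window Differential Methylation Analysis for Double-Enzyme RRBS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reduced representation bisulfite sequencing (RRBS)
    analysis built around a 100 bp sliding-window Mann-Whitney test for
    differentially methylated regions (DMRs). Includes an in-silico
    double-enzyme (MspI + ApeKI) reduced-representation digest with
    size-selection modelling, per-cytosine methylation call input/output in
    the CGmap dialect with CpG-context filtering and strand pooling,
    coverage and effect-size filtering with merging of significant windows
    into DMRs, cross-comparison reversal analysis (regions whose methylation
    change under one condition is reversed under another), priority-based
    genomic feature annotation, and a bisulfite methylome simulator with
    planted DMRs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
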