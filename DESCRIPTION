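Package: gctscreen
Title: Copy-Number and Expression Integration for Driver-Gene Screening in
    Adult-Type Granulosa Cell Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates array comparative genomic hybridization (CGH) log2
    ratio profiles with tumor transcriptomes to nominate candidate driver
    genes in small tumor cohorts. Provides tumor-cell-fraction-calibrated
    log-ratio thresholds, sliding-window CGH smoothing and large-scale
    imbalance calling, aneuploidy-aware expression normalization against
    non-carrier tumors, a Pearson-correlation-filtered amplified/deleted gene
    screen with frequent-CNV and full-inclusion filters, recurrent broken-gene
    detection from intragenic copy-number breakpoints, two-tailed Fisher exact
    co-occurrence tests for chromosomal alterations, complete-linkage
    expression clustering, and transcriptomic-neighbor network construction.
    Ships a seeded synthetic-cohort generator with planted ground-truth events
    so the whole pipeline is testable end to end.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
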