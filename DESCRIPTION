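Package: tedyn
Title: Transposable-Element Abundance and Small-RNA Targeting Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates per-subfamily transposable-element (TE) abundance from
    short-read hit counts against an exemplar database, classifies subfamilies
    into DNA / low-copy RNA / high-copy RNA groups with a log-normal mixture,
    tests abundance differences between accessions with a coverage-corrected
    chi-square, tests proportionality between copy number and siRNA targeting,
    and computes normalized log2 fold-change summaries. Ships a seeded
    synthetic-data generator emulating the count structure of maize genomic
    and small-RNA sequencing libraries so every step is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    utils,
    generics,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
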