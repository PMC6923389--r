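Package: adenoclone
Title: Oligoclonality and Low-Frequency Somatic Mutation Analysis for
    Uterine Adenomyosis Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterising uterine adenomyosis as an
    oligoclonal disorder from targeted deep amplicon sequencing and exome
    data. Implements a position-local background-noise caller for somatic
    single-nucleotide variants at ultra-low variant allele fractions
    (windowed per-position null with a one-sided normal tail test), hard
    filters for exome candidate variants, negative-panel hotspot cutoffs
    (mean + 3 SD), multi-region clonality matrices with mutation-sharing
    classification, bisulfite CpG methylation quantification, and cohort
    statistics (Fisher's exact test by the point-probability rule, Welch's
    t-test, comparative-Ct qPCR fold changes). Ships seeded generators for
    synthetic amplicon pileups, multi-region patients, negative panels,
    bisulfite reads and cohort metadata so the entire pipeline runs and is
    tested without external data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Rsamtools,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
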