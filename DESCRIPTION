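Package: cfdnafoot
Title: Nucleosome Occupancy and Transcription Factor Footprints in Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed nucleosome-occupancy analysis for low-pass whole-genome
    sequencing of plasma cell-free DNA. Reads aligned cfDNA fragments (BAM or
    BED), applies the nucleosome-protection length filter, computes
    depth-normalized occupancy over fixed genomic windows, calls gained- and
    lost-nucleosome regions between treatment conditions with a
    stability-filtered two-threshold procedure, profiles aggregate coverage
    around transcription factor binding sites, scores per-sample TF activity
    by binding-site center read depth, relates activity to tumor expression
    and cfDNA tumor fraction, and summarizes fragment-size-distribution peak
    ratios. Includes a synthetic cfDNA cohort generator with planted
    differential windows, tumor-fraction-scaled TF footprints and linked
    expression, so every stage of the analysis is verifiable without
    controlled-access patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
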