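Package: ztakit
Title: Locus- and Transcript-Resolved Analysis of Zygotic Transposable-Element Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when and how transposable elements (TEs) are
    transcribed during early embryonic development from long-read transcript
    catalogs. Classifies transcript models into TE-alone, TE-gene chimeric and
    gene classes from exonic overlap with a RepeatMasker annotation, calls
    maternal versus zygotic status and activation stages from staged expression
    matrices, clusters activation trajectories and scores within-subfamily
    heterogeneity by entropy, computes relative nuclear/cytoplasmic localization
    statistics, and dates and diagnoses TE copies (Kimura two-parameter
    divergence, Jukes-Cantor LTR insertion ages, intactness, strain-based age
    groups, transposition versus segmental-duplication origin). A synthetic-data
    generator produces every input with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
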