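Package: djdose
Title: Dosage Genotyping of the rDNA Distal Junction for Robertsonian
    Translocation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates the diploid copy number of the acrocentric rDNA
    distal junction (DJ) and related targets from short-read alignments
    under several read-depth normalization modes, and reference-free from
    k-mer multiplicity spectra. Harmonizes estimates across reference
    builds with an ordinary-least-squares calibration, classifies samples
    into discrete DJ-copy bins with a fixed-mean, variance-constrained
    Gaussian mixture model fitted by bootstrapped EM, and provides
    closed-form false-positive and false-negative rate models for
    Robertsonian translocation screening. Ships seeded simulators for
    alignments, k-mer spectra and copy-number cohorts so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    graphics,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
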