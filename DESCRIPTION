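Package: indexhop
Title: Simulation, Detection and End Attribution of Index Swapping in
    Dual-Indexed Sequencing Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing sample index swapping ("index
    hopping") in pooled libraries sequenced on patterned flow cells.
    Simulates pooled dual-index reads with configurable per-end swap
    rates, index sequencing error, and swap-correlated fragment
    covariates (insert length, GC, chimerism) with full ground truth;
    demultiplexes index-read pairs against non-redundant dual-index
    sample sheets with a mean-quality filter and mismatch-tolerant
    matching; tabulates swapped index combinations per sample pair and
    per flow-cell tile; and estimates end-specific (i5 versus i7) swap
    probabilities from two-organism mixture designs by proportional
    allocation of undetermined swaps.  Also validates and designs
    dual-index sets under Hamming-distance, GC-content, homopolymer and
    per-cycle color-balance constraints.
License: MIT + file LICENSE
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
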