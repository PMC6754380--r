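Package: linkrec
Title: Crossover Detection and Recombination Maps from Linked-Read Gamete Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic recombination crossovers from linked-read
    (droplet barcode) sequencing of pooled gametes of a single individual.
    Reconstructs high-molecular-weight molecules from barcoded reads, phases
    heterozygous variants into the two parental haplotypes by minimum error
    correction over molecules, scores each molecule as haplotype 1, haplotype 2
    or recombinant with a one-switch mixture likelihood, and calls crossover
    intervals bounded by flanking informative variants. Includes windowed
    recombination maps with centimorgan estimates, coldspot scans, hotspot
    clustering and feature-proximity permutation tests, and a desk-scale
    gamete linked-read simulator with planted crossovers and barcode
    collisions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
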