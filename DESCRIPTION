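Package: rohscape
Title: Regions of Homozygosity from Re-Sequencing Data and Their Genomic Landscape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects regions of homozygosity (ROHs) in individual diploid
    genomes from whole-genome re-sequencing data using coverage-corrected
    heterozygosity in 10-kb bins and a calibrated sliding-window caller with
    per-bin relaxation and uncovered-bin rules. Computes per-individual
    nucleotide diversity inside and outside ROHs, chromosomal-landscape
    profiles (GC content, recombination rate, ROH density over relative
    chromosomal position) and their correlations, shared-ROH regions across
    individuals with gene overlap and hypergeometric term enrichment, and a
    comparison against array-based ROH tables. Includes a synthetic-data
    generator with planted autozygous tracts so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
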