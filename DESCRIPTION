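Package: glaucokit
Title: Phylogenomic and Genome-Diagnostic Screens for Glaucophyte Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the computational screens
    used in glaucophyte (Cyanophora-type) genome analysis: single-copy
    orthogroup filtering and concatenated supermatrix construction for
    eukaryote-wide phylogenomics, a deterministic gene-tree classifier for
    chlamydial horizontal gene transfer candidates, a six-frame screen for
    bidirectional overlapping open reading frames on transcripts, a SNP
    allele-frequency-band ploidy diagnostic with an exact binomial diploid
    null, and the light/dark time-course differential-expression and
    clustering rule. Ships seeded synthetic-data generators emulating the
    statistical structure each stage assumes, so every stage is testable
    without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    DESeq2,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
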