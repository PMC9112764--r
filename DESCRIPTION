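Package: plrforge
Title: Reference-Guided Pseudo-Long Reads from Metagenomic Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates pseudo-long reads (PLRs) from short-read alignments
    against microbial reference genomes. Mapped reads are filtered and piled
    up per reference position, references are broken at uncovered regions
    into PLR containers, each container's column alignment is converted to a
    graph of normal nodes and single-column bubbles, bubble-linking fragments
    are clustered by a consistency distance to recover co-occurring variant
    combinations, and one variant-aware long sequence is emitted per
    combination. Includes a self-contained simulator of strain mixtures
    (references, haplotypes, paired-end reads, ground-truth alignments) for
    testing, plus FASTA/BED/TSV writers and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
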