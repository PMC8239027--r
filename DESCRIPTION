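Package: asmrec
Title: Consensus-Based Genome Assembly Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and corrects scaffolding misjoins in a long-read genome
    assembly by consensus against independent de novo assemblies of the same
    genome, replaces misjoined blocks with alternate-assembly sequence to form
    a hybrid assembly, fills N-gap tracts from gap-free alternate regions, and
    merges scaffolds supported by alternate-assembly adjacency. Includes a
    minimizer-anchor chaining aligner with PAF import/export, AGP v2.1
    provenance output, NX/N50 contiguity statistics, BAC-end (large-insert)
    read-pair concordance validation, and a seeded simulator that generates
    truth genomes, corrupted base assemblies and alternate assemblies with
    machine-readable truth records so every correction is checkable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
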