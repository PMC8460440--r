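Package: potworm
Title: Horizontal Gene Transfer Detection, Gene-Family Expansion Scores and
    Assembly Statistics for Annelid Genome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the downstream computational
    analyses of an annelid (potworm, Enchytraeus crypticus) genome project.
    Implements a staged horizontal-gene-transfer (HGT) detection pipeline
    built on h-scores (best non-metazoan minus best metazoan BLAST bitscore),
    genomic-context linkage with long reads, a bitscore confirmation rule and
    a smallest-clade phylogenetic test; orthogroup gene-family
    expansion/contraction z-scores with lineage-specific and shared-family
    accounting; assembly summary statistics (N50/L50/GC, genome fractions)
    and a k-mer containment screen for mitochondrial fragment scaffolds; and
    seeded synthetic-data generators with planted ground truth so every stage
    is testable without external downloads.
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
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
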