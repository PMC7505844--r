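Package: synovitcr
Title: Paired-Chain Single-Cell TCR Clonality and Convergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-cell T-cell receptor (TCR) repertoire analysis
    of paired compartments (e.g. blood versus synovial fluid). Reads
    10x-CellRanger-style VDJ contig annotation tables and AIRR rearrangement
    files, partitions chains per cell barcode with explicit multiplet rules,
    calls clonotypes on combined alpha/beta CDR3 nucleotide sequences, tests
    per-clone tissue enrichment (Fisher's exact test with Benjamini-Hochberg
    correction) and clone-phenotype-cluster association (Bonferroni), builds
    GLIPH-style TCR convergence groups from CDR3 motif enrichment against a
    naive reference repertoire, computes equal-patient-weight V-J usage
    matrices, applies droplet and plate cell QC filter presets, and performs
    paired analyte panel statistics. Ships a synthetic paired-repertoire
    generator with planted ground truth so every stage is testable without
    patient data.
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
    igraph,
    Matrix,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
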