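Package: scafkit
Title: Homology-Based Genome Assembly Correction, Scaffolding, Patching and Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for improving draft genome assemblies with pairwise
    whole-genome alignments: misassembly detection and correction with
    optional read-coverage validation, reference-guided ordering and
    orienting of contigs into scaffolds with confidence scoring and gap-size
    inference, gapless assembly patching through a directed scaffold graph,
    and reconciliation of multiple AGP scaffolding solutions with optional
    Hi-C contact re-weighting. Includes readers, writers and validators for
    PAF, MUMmer delta, AGP v2.1, FASTA and GFF3 intervals, assembly
    contiguity (nX) statistics, and deterministic synthetic-assembly
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    stringr,
    tibble
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
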