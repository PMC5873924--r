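Package: splicegauge
Title: Genome-Wide Intron Retention and Alternative Splicing Changes from
    RNA-seq Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects genome-wide alternative-splicing changes (intron
    retention, more-efficient splicing, exon skipping, alternative donor and
    acceptor sites) and differentially expressed genes between a mutant and a
    wild type from per-replicate SAM alignments and GFF3 gene annotation.
    Applies explicit alignment acceptance filters (identity, terminal exact
    matches, minimum block length), derives per-base depth, splice-junction
    and per-gene read-count evidence, tests intron-retention ratios and
    junction-defined events with replicate-level Welch t-tests, normalizes
    counts by trimmed mean of M-values (TMM) into logCPM and RPKM, and
    quantifies the splice variants of a dual-intron reporter locus whose
    alternative 3' splice sites lie a few nucleotides apart. Ships a
    deterministic spliced-read simulator with ground-truth logs so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    rtracklayer,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
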