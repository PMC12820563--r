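Package: foxpair
Title: Paired-Motif Discovery and Head-to-Head Topology Analysis for
    FoxP-Family Pull-Down Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering head-to-head (H-H) DNA
    motifs bound by FoxP-family transcription factors from degenerate-oligo
    pull-down sequencing (PD-seq), and for quantifying paired-motif
    enrichment, gap-size preference, and the topology of H-H sites relative
    to TnG-repeat microsatellites in genomic interval sets.  Includes
    degenerate (IUPAC) sequence primitives, read extraction and RPM count
    tables for the two PD-seq library designs, degenerate "2N motif"
    enumeration and ranking, oriented pair-pattern construction with
    shift-aware counting and analytic baseline correction, genome interval
    scanning with exact-binomial enrichment against background intervals,
    TnG-repeat detection with aligned/divergent topology classification and
    coverage stratification, gene-proximity association profiles, and seeded
    synthetic-data generators with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
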