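Package: spliceward
Title: Splice-Junction-Centric Simulation, Quantification and Comparison of
    RNA-Seq Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for splice-junction-centric analysis of RNA-Seq data:
    an RNA-Seq read simulator driven by empirical, position-specific
    sequencing-error models, with origin-encoding read identifiers and full
    truth reporting; a junction quantifier that streams spliced alignments
    and computes alignment diagnostics (offset Shannon entropy, minimum
    match on either side, exon/intron shoulder repeat identity, donor and
    acceptor motif strand inference, gene assignment, intron read-through)
    together with qualitative and quantitative post hoc filters against
    diagnosed aligner error classes; a pairwise splicing-event builder that
    enumerates splice-graph bubbles from transcript models, maps each event
    to disjoint inclusion and exclusion junction sets and quantifies
    percent-spliced-in (PSI); and an event comparison framework using
    Fisher's exact test on junction counts with Benjamini-Hochberg FDR
    control and conservative differential-splicing call filters. A
    deterministic toy-fixture generator supplies synthetic genomes,
    annotations and planted error structures so the whole pipeline is
    testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
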