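Package: scisorpipe
Title: Single-Cell Iso-Seq Read Processing and Annotation Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for annotating genomes with barcoded full-length
    single-cell isoform reads (ScISOr-Seq). Processes circular-consensus
    reads from 10x 3' gene-expression libraries (sample-barcode clipping,
    primer detection and orientation, cell-barcode and UMI extraction,
    polyA trimming, duplicate removal), collapses splice-aware alignments
    into unique transcript models by intron-chain identity, classifies
    isoforms against a reference annotation using SQANTI-style structural
    categories (FSM, ISM, NIC, NNC, fusion, genic, intergenic) with
    intra-priming and RT template-switching artifact filters, merges the
    resulting models with the reference into unified gene models, and
    quantifies strand-aware 5'/3' gene-end shifts and terminal-exon read
    counts between annotations. Includes a deterministic synthetic-data
    generator (genomes, annotations, barcoded reads, alignments) with
    complete truth tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
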