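Package: fanalign
Title: Fanned Multi-Reference Smith-Waterman Realignment for Fusion Breakpoint Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Realigns RNA-seq reads around a candidate gene-fusion breakpoint
    against arbitrary panels of 5-prime and 3-prime reference sequences using a
    "fanned" variant of Smith-Waterman local alignment: one score matrix per
    reference on each side, converging into a shared breakpoint column and
    fanning out again, so that a single read may start in any 5-prime reference
    and continue across the junction into any 3-prime reference. Includes
    exon-aware retrieval of genomic and exonic flanking references from a local
    indexed FASTA plus exon annotation, extraction of breakpoint-proximal reads
    (and their mates) from coordinate-sorted indexed BAM files, score and
    spanning-read filters, a color-coded SVG/HTML evidence plot with
    machine-readable TSV/JSON tables, and a seeded synthetic-locus generator
    for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
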