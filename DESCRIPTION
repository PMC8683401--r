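Package: famscreen
Title: Gene-Family Mining with PROSITE-Style Motif Keys
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for genome-wide identification and characterization of
    plant gene families, built around the cyclic nucleotide-gated channel
    (CNGC) family of Brassica rapa. Parses and scans PROSITE-dialect motif
    patterns against protein sequences, induces consensus motif keys from
    multiple sequence alignments at a conservation threshold, screens
    candidate family members by length and domain criteria, computes
    ProtParam-style physicochemical protein profiles (molecular weight,
    isoelectric point, instability and aliphatic indices, GRAVY, charge,
    compositions), annotates exon/intron structure and intron phases from
    GFF3, detects tandemly duplicated gene pairs from chromosomal
    coordinates, and classifies expression fold changes from FPKM matrices.
    Ships transcribed coordinate and property tables for the 29-member
    BrCNGC family plus seeded synthetic-data generators so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
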