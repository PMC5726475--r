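Package: coiassembler
Title: Full-Length COI Barcode Assembly from Pooled Tagged Amplicon
    Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles full-length (658 bp) mitochondrial Cytochrome c
    oxidase subunit I (COI) reference barcodes for up to 96 individually
    tagged specimens from a single pooled, fragmented short-read library.
    Reads are demultiplexed by dual 5-bp inline tags plus primer matching,
    per-well terminus consensus anchors are built from overlapped read
    pairs, and the interior of each barcode is reconstructed by a targeted
    de Bruijn graph walk between the 5' and 3' anchors with abundance- and
    read-support-based path pruning.  A companion route demultiplexes
    PacBio circular consensus (CCS) reads and picks per-well barcodes by
    pass-filtered identical clustering.  Post-assembly checks cover
    reading-frame validation under the invertebrate mitochondrial code,
    comparison against Sanger references with IUPAC-ambiguity resolution,
    and classification of co-amplified nontarget sequences (Wolbachia-like
    contaminants, NUMTs, cross-contamination).  A deterministic plate
    simulator generates tagged amplicon libraries with ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
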