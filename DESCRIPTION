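Package: mitocr
Title: Structural Characterization of Mitochondrial Genomes: Gene Order,
    Control-Region Domains and Repeated Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural characterization of vertebrate
    mitochondrial genomes, with an emphasis on gecko lizards. Reads
    annotated mitogenomes from GenBank flat files, normalizes gene naming
    into a controlled vocabulary, classifies circular gene orders into the
    six rearrangement types described for gekkotan mitogenomes (canonical
    order, tRNA-Gln/ND4 duplication, supernumerary light-strand
    replication origins, tRNA-Glu translocation or deletion, and large
    block duplication), partitions the control region into ETAS, CCR and
    CSB domains using degenerate consensus motifs (TAS, CSB-F, CSB-1/2/3),
    detects variable-number tandem-repeat arrays and decomposes long
    repeat units into base-unit multiples, scans microsatellites and
    inverted-repeat stems, and computes base-composition skew statistics
    and uncorrected p-distances. A synthetic-mitogenome generator with
    full ground-truth records makes every stage testable without
    downloading sequence data.
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
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
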