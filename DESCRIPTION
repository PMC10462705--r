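Package: eccsv
Title: Extrachromosomal Circular DNA and Structural Variant Analysis from
    Long-Read Mobilome and Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the extrachromosomal circular DNA (eccDNA)
    compartment and associated genomic structural variants from long-read
    sequencing of plants with reactivated transposable elements (TEs).
    Decomposes rolling-circle-amplification concatemer reads into monomers
    and classifies circle structure (full-length, domain-truncated and
    chimeric TE circles); calls TE insertion polymorphisms from
    CIGAR-bearing alignments with read-support clustering and target-site
    duplication (TSD) validation; detects tandem duplications from split
    reads and small deletions with control subtraction; quantifies eccDNA
    evidence per TE family with artifact filtering and RPM/FPKM
    normalization. A bundled simulator generates synthetic references,
    implanted variants, circle templates, concatemer and spanning reads,
    and ground-truth PAF alignments so the whole pipeline is testable
    without external data.
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
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
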