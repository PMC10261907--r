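Package: fuseval
Title: Supervised In Silico Evaluation of Candidate Fusion Transcripts
Version: 0.1.0
Authors@R:
    person("Fuseval", "Developers", email = "fuseval@example.org", role = c("aut", "cre"))
Description: Re-evaluates the RNA-seq read alignment evidence for candidate
    gene-fusion transcripts. Builds intron-shrunk two-gene fusion contigs with
    invertible genome/contig coordinate maps, classifies aligned fragments as
    breakpoint-defining split reads, spanning fragments or unfused-partner
    counter-evidence under per-read quality rules, fractionally assigns
    ambiguous spanning fragments across fusion variants with an
    expectation-maximization algorithm, computes sequence and expression
    features (FFPM, fusion allelic ratios, splice-site agreement, k-mer
    microhomology proximity), applies minimum-evidence and promiscuity
    filters, and clusters/classifies fusion variants into COSMIC-like,
    artifact-like or other categories via a k-nearest-neighbor graph, Leiden
    community detection and a random forest. Ships a synthetic-data simulator
    emitting genomes, annotations, reads and truth tables so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    FNN,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
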