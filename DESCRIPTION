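Package: readdist
Title: Alignment-Free and Alignment-Based Distances Between Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes read-to-read distances for short sequencing reads: an
    alignment-free distance based on the Euclidean distance between tetramer
    (k-mer) frequency vectors, a Needleman-Wunsch global-alignment distance, a
    word-seeded local-alignment distance, and a reference-overlap ("Bowtie")
    distance derived from read placements on a reference genome. Includes a
    read simulator with known placements, percentile threshold predictors of
    the overlap distance with ROC/AUC evaluation and cross-validation, and
    readers/writers for FASTA, FASTQ, SAM and tabular pair-distance files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
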