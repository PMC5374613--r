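Package: kmerbin
Title: Two-Phase Minimizer-Binned k-mer Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact counting of k-mers in FASTA/FASTQ sequencing reads,
    including very large k (hundreds of bases), via a two-phase
    disk-backed pipeline: reads are decomposed into super-mers that share
    a common minimizer and binned into temporary files, then each bin is
    counted with open-addressing hash tables that use bounded quadratic
    probing, adaptive table sizing from a running distinct/total ratio,
    multi-pass splitting under a memory cap, and failure buffers that
    guarantee no k-mer is lost. Several total orderings on minimizers
    (plain lexicographic, CGAT, Roberts, KMC2-style, random, and
    distance-from-pivot) are provided together with metrics to compare
    them, a seeded read simulator, and a brute-force oracle counter for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
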