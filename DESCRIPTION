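Package: olcassembler
Title: Overlap-Layout-Consensus Assembly of Paired-End Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale overlap-layout-consensus (OLC) de novo assembler for
    paired-end short-read libraries. Reads and their reverse complements form
    double vertices of an overlap graph whose arcs are verified by semi-global
    Needleman-Wunsch alignment; candidate pairs are preselected with k-mer
    characteristic fingerprints, smallest lexicographical descriptors, and
    paired-end/successor propagation. Contigs are grown by a state-voting
    graph traversal with forward/backward fork detection that distinguishes
    repeat forks from sequencing-error and SNP forks, then corrected with a
    greedy hyper-heuristic driven by paired-end anomalies, and trimmed of
    overlapping ends for downstream scaffolding. Includes a paired-end read
    simulator with planted repeats, SNPs and chimeras, and lightweight
    reference-based evaluation metrics (NG(X), genome fraction, duplication
    ratio, misassembly detection).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
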