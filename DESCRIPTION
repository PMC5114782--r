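Package: codonCDS
Title: Full-Length Coding Sequence Assembly from Unassembled
    Transcriptome Reads with Codon-Based de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs full-length coding sequences (CDSs) directly from
    unassembled transcriptomic reads. Reads are six-frame translated into
    stop-free, codon-aligned candidate open reading frames (ORFs); a
    support vector machine trained on codon-usage features, with a
    self-supervised training set derived from a de Bruijn graph of
    strictly translated ORFs, separates coding from spurious frames; all
    candidate ORFs are then assembled on a codon-based de Bruijn graph
    (k-mers sampled every 3 nt so every node stays in frame), simplified
    by tip trimming and bubble merging, and traversed between
    SVM-approved landmark k-mers to emit CDSs. Also provides the
    evaluation statistics used for CDS prediction benchmarks (redundancy,
    ROC point, fragment number, base error rate, chimera rate, ortholog
    pair classification; BLAT PSL ingestion) and a synthetic-data
    generator for codon-biased CDSs, gene models and error-bearing short
    reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    e1071,
    igraph,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
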