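Package: circflow
Title: Full-Length Assembly and Quantification of Circular RNA Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs full-length circular RNA (circRNA) isoforms from
    spliced paired-end RNA-seq alignments and a list of back-splice
    junctions, and quantifies their expression. For every back-splice
    event in a gene locus a directed acyclic splice graph is built from
    annotated exon boundaries and gap-containing read alignments; the
    minimal set of source-to-sink paths covering all nodes, edges and
    read-witnessed subpaths (an extended minimum path cover) yields the
    candidate isoforms, whose relative abundances are then estimated by
    an expectation-maximization algorithm on a circular-transcript
    likelihood with wrap-around fragment lengths. Includes a paired-end
    read simulator with known ground truth, evaluation utilities
    (sensitivity, precision, F1, correlation), and a relation index
    summarising the genomic overlap complexity of back-splice junctions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
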