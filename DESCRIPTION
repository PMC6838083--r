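Package: cliqueref
Title: Reference Gene Selection for RT-qPCR by Pairwise Equivalence Tests
    and Maximal Cliques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects stable reference (housekeeping) genes from RT-qPCR
    quantification-cycle (Cq) data while respecting its compositional
    nature. Every pairwise log-ratio of candidate genes is subjected to a
    two one-sided t-test (TOST) of equivalence between two groups; gene
    pairs proven equivalent form the edges of an undirected graph, and the
    intersection of its maximum cliques is returned as the reference set.
    Includes triplicate quality control (failure flagging and outlier
    elimination), Monte-Carlo calibration of the per-test rejection cutoff
    against a family-wise spurious-clique error rate, reimplementations of
    the geNorm and NormFinder stability rankings for comparison, a
    synthetic Cq data generator with known ground truth, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
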