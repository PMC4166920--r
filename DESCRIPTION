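Package: wgdortho
Title: Classifying Gene Homology After Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether a gene from a lineage of uncertain
    post-polyploidy history is a 1:1 ortholog of either of the two
    duplicate ("a"/"b") clades produced by an ancient whole-genome
    duplication, or an outgroup to both.  Builds constrained topology
    hypotheses by exhaustive query placement on a fixed species backbone,
    scores them with per-site amino-acid log-likelihoods (Felsenstein
    pruning under a reversible model with discrete-gamma and invariant
    rate heterogeneity), adjudicates them with the approximately unbiased
    (AU) test via multiscale RELL bootstrap, and decomposes site-wise
    signal into a three-axis likelihood-ratio table to detect conflicting
    (trifurcating) support within a locus or gene cluster.  Includes a
    synthetic-data generator for shared versus lineage-independent
    diploidization scenarios with exact ground truth, alignment trimming
    and concatenation utilities, a conserved-element identity-window
    scanner, and cluster-level reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
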