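Package: learnpair
Title: Learning-Pair Models of Stochastic Whole-Profile Gene Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulators and architecture-building tools for learning-pair
    models of gene regulation, in which pairs of factors repeat stochastic
    competitive amplification and error-dependent binomial decay so that
    whole-profile expression ratios autonomously approach a target ratio.
    Includes a single-pair and flat-list simulator, hierarchical binary
    pair architectures with per-pair independent learning, agglomerative
    clustering with area- and coefficient-of-variation-based linkage
    distances for building architectures from expression matrices, an
    mRNA-pool variant with tree-descent transcription, and synthetic
    profile generators emulating RNA-seq-like targets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
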