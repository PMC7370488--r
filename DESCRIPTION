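Package: distimpute
Title: Machine Learning Imputation of Incomplete Phylogenetic Distance
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating phylogenetic trees when the pairwise
    evolutionary distance matrix has missing entries.  Implements two
    imputation methods: regularized matrix factorization trained by
    stochastic gradient descent over the observed entries, and an
    undercomplete autoencoder trained with a masked reconstruction loss
    and iterative blending of predictions into the missing cells.  Also
    provides TN93 and LogDet distance estimation from multiple sequence
    alignments with pairwise deletion, direct (random entry deletion)
    and indirect (gene removal) missingness generators, neighbor-joining
    tree construction, normalized Robinson-Foulds tree comparison,
    sequence simulation along random trees, and a replicated
    benchmarking pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    seqinr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
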