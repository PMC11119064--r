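Package: fcnet
Title: Graph Convolutional and Adversarial Classifiers for Functional
    Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of subjects from resting-state functional
    connectivity (FC) correlation matrices. Implements a spectral graph
    convolutional network with self-attention (top-k) graph pooling and
    phenotype fusion, a conditional auxiliary-classifier generative
    adversarial network whose generator produces valid FC matrices through
    an inner product of region embeddings and whose discriminator is a
    BrainNetCNN (edge-to-edge, edge-to-node, node-to-graph filters), the
    shared backbone-graph construction (mean training FC, edge-retention
    curve, elbow threshold, symmetric normalization), a holdout plus
    cross-validation evaluation protocol with macro one-vs-rest metrics,
    exact binomial and Wilcoxon rank-sum significance tests, and a
    synthetic-cohort generator with planted class effects for end-to-end
    testing without restricted clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
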