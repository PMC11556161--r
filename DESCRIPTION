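Package: scoremol
Title: Score-Based Generative Diffusion Models for 3D Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time score-based generative modelling of small 3D
    molecules. The joint distribution over one-hot atom types, center-of-mass
    free Cartesian coordinates and a symmetric weighted bond adjacency is
    diffused by three coupled variance-preserving stochastic differential
    equations, and three E(3)-equivariant partial-score networks (equivariant
    graph convolutions augmented with inter-atomic cosine features, plus graph
    multi-head attention over adjacency powers) are trained by denoising score
    matching. Generation uses a Predictor-Corrector reverse-SDE sampler
    followed by discrete decoding. Includes SDF/XYZ input and output, a
    synthetic rigid-template fixture generator, and validity, uniqueness and
    stability evaluation metrics with geometry-based bond inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    tools,
    graphics,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    ChemmineR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
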