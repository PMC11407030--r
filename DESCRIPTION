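Package: agetr
Title: Approximated Gene Expression Trajectories and GRN Reverse-Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs per-cell approximated gene expression trajectories
    (AGETs) by registering fixed-sample 3D expression point clouds onto
    live-imaging cell tracks, then reverse-engineers a three-gene, two-signal
    gene regulatory network by simulating a connectionist ODE model in every
    tracked cell ("live-modelling") and fitting its 24 parameters with an
    affine-invariant ensemble MCMC sampler. Includes posterior filtering,
    k-means topology clustering, in-silico signal-perturbation experiments,
    and a synthetic presomitic-mesoderm data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    zoo,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
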