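Package: phylomorph
Title: Geometric Morphometrics and Phylogenetic Least Squares with
    Permutation Inference
Version: 0.1.0
Authors@R:
    person("First", "Last", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of multi-module 3-D landmark
    data in a phylogenetic framework: Generalized Procrustes Analysis per
    anatomical module, principal components of shape, multivariate
    phylogenetic generalized least squares with residual-randomization
    permutation inference (RRPP), univariate GLS term tests on principal
    component scores, phylogenetic two-block partial least squares against
    diet-proportion data, multivariate Brownian-motion simulation on trees,
    and a robustness experiment that measures Type-I error of PGLS on
    high-dimensional shape data under label permutation. A synthetic-data
    generator produces trees, ecology tables and landmark datasets with
    known structure so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
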