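Package: opershape
Title: Phylogenetic Geometric Morphometrics of Opercle-Like 2-D Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the macroevolution of 2-D landmark shapes,
    built around the teleost opercle bone but applicable to any flat
    structure digitised as fixed landmarks plus edge semilandmarks.
    Provides TPS/CSV landmark input, generalized Procrustes
    superimposition, principal-component morphospaces with nonparametric
    density landscapes, phylomorphospace layouts with squared-change
    parsimony ancestral states, multivariate phylogenetic signal (Kmult),
    Procrustes-variance disparity and multivariate evolutionary-rate
    contrasts with permutation/simulation tests, Brownian motion /
    Ornstein-Uhlenbeck / early-burst / white-noise model selection by
    AICc, Stayton C1-C5 convergence metrics with Brownian-motion null
    simulations, an elliptical-Fourier outline cross-check, and a
    synthetic-data generator producing landmark datasets with known
    evolutionary ground truth on simulated time trees.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
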