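Package: spatzip
Title: Bayesian Spatial Models for Zero-Inflated Disease Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Disease mapping for areal count data with excess zeros.
    Fits zero-inflated Poisson models (structural-zero hurdle and
    mixture variants) and a joint Bernoulli/zero-truncated-Poisson
    model in which a single BYM or BYM2 spatial random effect is
    shared between the occurrence and count processes, the shared
    effect entering the occurrence predictor through a scaling
    coefficient. Includes scaled intrinsic CAR precision matrices,
    penalized-complexity priors for the BYM2 precision and mixing
    parameters, an adaptive MCMC engine for posterior inference,
    DIC and CPO-based logarithmic-score model comparison, and a
    lattice-based simulation study for parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
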