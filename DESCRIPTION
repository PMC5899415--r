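Package: ssblend
Title: Blended Single-Step Relationship Matrices for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and analysis of the single-step relationship
    matrix H that combines a pedigree numerator relationship matrix A with
    a VanRaden genomic relationship matrix G, with scalar blending weights
    tau and omega applied on the level of the inverse. Provides the
    explicit covariance-level form of the blended matrix and its genotyped
    block, classification of the positive semi-definite (tau, omega)
    region, Loewner-order monotonicity diagnostics, BLUP solvers for the
    single-step mixed model (direct and preconditioned conjugate
    gradient), cross-validated grid search over the blending weights with
    predictive-ability and inflation (dispersion-slope) metrics, and a
    pedigree-linked population simulator with Mendelian gene dropping so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
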