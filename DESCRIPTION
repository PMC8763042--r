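Package: catsreg
Title: Generalized Community Assembly by Trait Selection (CATS) Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits community assembly by trait selection (CATS) regressions:
    exponential-family generalized linear models of species abundance on
    traits, with meta-community relative abundances carried into the model
    as offsets constructed correctly for any link function. Supports
    Gaussian, Poisson, binomial (including the constrained log-binomial
    case), negative binomial, Tweedie (1 < p < 2) and zero-truncated count
    families, two-part hurdle models, Kullback-Leibler R-squared with
    offset-aware null conventions, a deviance-based adjusted R-squared, and
    partitioning of explained variation into pure local-selection, pure
    meta-community, joint, and unexplained components. Includes randomized
    quantile residual diagnostics and synthetic community generators for
    method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
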