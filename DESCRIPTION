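Package: glmqc
Title: Qualitatively Constrained Generalized Linear Models for
    Heterogeneous Treatment Effect Targeting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits generalized linear models with qualitative (sign and
    monotonicity) constraints on the effects of discretized covariates,
    using an incremental-coding reparameterization that turns shape
    constraints into simple sign bounds solved by box-constrained
    iteratively reweighted coordinate descent.  On top of the constrained
    model the package provides S-learner estimation of heterogeneous
    treatment effects for an ordinal treatment, a two-component consensus
    ensemble, log-odds-ratio explanation of black-box effect estimates via
    an additive surrogate with pairwise terms, budget-constrained
    benefit-to-cost targeting with benefit-capture curves, and a
    synthetic confounded health-survey generator with exact ground-truth
    effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
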