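Package: rtcondep
Title: Conditional Dependence Between Response Time and Accuracy
Version: 0.1.0
Authors@R: person("rtcondep", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint hierarchical models for item response accuracy and
    response time that relax the conditional independence assumption of
    the standard hierarchical framework.  Implements probit item response
    models in which the item characteristic curve parameters are linear,
    quadratic, or piecewise-constant (multiple-category) functions of the
    standardized residual log response time, estimated by
    Metropolis-within-Gibbs sampling with probit data augmentation.  Also
    provides a kernel-weighted nonparametric moderation estimator of the
    item slope and intercept as functions of residual log response time,
    permutation tests of conditional independence, and posterior
    predictive checks of linearity, together with a simulator for all
    generative models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
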