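Package: anyprev
Title: Multivariate Bayesian Meta-Analysis of Superordinate Category Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the prevalence of a superordinate category of disorders
    ("any of D disorders") from meta-analytic aggregate counts and, where
    available, individual participant diagnoses. Fits a hierarchical Bayesian
    multivariate model with a binomial-probit likelihood, correlated
    probit-scale study effects with LKJ correlation priors, and a latent
    multivariate-probit comorbidity layer for individual participant data.
    Category-level quantities (probability of at least k disorders,
    conditional comorbidity probabilities, per-study posterior predictions)
    are obtained by posterior simulation of hypothetical cohorts. Also
    provides the univariate logit-scale REML random-effects and
    meta-regression comparators implemented from first principles, a
    synthetic meta-analysis generator emulating the study-level measurement
    process, and a coverage/bias evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
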