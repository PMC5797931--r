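Package: poppkdual
Title: Population Pharmacokinetics of Sublingual Desmopressin with Dual-Input
    Two-Compartment Absorption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear mixed-effects (FOCE) analysis pipeline for a sublingual
    desmopressin lyophilisate in growing piglets: a dual-input two-compartment
    structural model (zero-order release into a buccal depot with first-order
    absorption, plus a lagged first-order gastrointestinal depot), hierarchical
    population layer with centered power covariate models, first-order
    conditional estimation with covariance step and empirical Bayes posthoc
    estimation, stepwise covariate modeling, goodness-of-fit and visual
    predictive check diagnostics, non-compartmental secondary parameters, and a
    synthetic-cohort generator emulating the study design so the whole pipeline
    is testable without real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
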