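Package: dcmnet
Title: Bilinear Dynamic Causal Modelling of a Frontal Motor Network with
    Group Bayesian Model Selection and Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and inverts bilinear dynamic causal models (DCM) of
    BOLD fMRI responses in a four-region frontal motor network (prefrontal
    cortex, lateral premotor cortex, pre-supplementary motor area, primary
    motor cortex) engaged by specified versus freely chosen actions.
    Provides a 48-model space varying intrinsic connectivity structure and
    contextual (psychophysiological-interaction) modulation, a balloon-model
    haemodynamic forward model, variational-Laplace model inversion with a
    free-energy bound on log model evidence, fixed-effects and hierarchical
    Dirichlet random-effects group Bayesian model selection with exceedance
    probabilities, a test-retest reliability battery for connectivity
    parameters (cross-session correlations, sign-consistency chi-squared
    tests, repeated-measures ANOVA, posterior-correlation summaries), and a
    synthetic-cohort generator emulating healthy young, healthy older and
    Parkinson's disease (on/off medication) study arms with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
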