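Package: dexpoppk
Title: Population Pharmacokinetics of Dexmedetomidine Infusions in the ICU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of dexmedetomidine
    administered by continuous intravenous infusion during ICU analgosedation.
    Implements a closed-form two-compartment disposition model under arbitrary
    piecewise-constant infusion schedules, nonlinear mixed-effects estimation
    (FOCE with interaction, or Laplace) with lognormal inter-individual
    variability and proportional residual error, stepwise covariate selection
    gated on eta-shrinkage, nonparametric case-resampling bootstrap, and
    prediction-corrected visual predictive checks. Includes a synthetic-cohort
    generator reproducing an ICU infusion study design (weight-scaled variable
    infusion rates, two arterial sampling protocols) so the full pipeline can
    be exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
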