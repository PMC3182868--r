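Package: il21pkpd
Title: Integrated Disease/PK/PD Modeling of Systemic IL-21 Immunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and calibration pipeline for systemic interleukin-21
    (IL-21) immunotherapy of murine solid tumors (B16 melanoma, RenCa renal
    carcinoma). Couples a semi-physiological multi-compartment pharmacokinetic
    model with saturable transition and degradation kinetics to a target-tissue
    pharmacodynamic and disease system (NK and CTL effectors, cytotoxic-protein
    stores, drug-induced memory, logistic tumor growth). Provides fixed-step
    fourth-order Runge-Kutta integration with bolus dosing events, Hooke-Jeeves
    pattern-search calibration with Latin-hypercube multi-start ensembles and
    prediction-consistency acceptance, sequential four-stage parameter
    estimation, in-silico regimen scans (therapy onset, iso-dose fractionation,
    daily-dose titration), and a seeded virtual-cohort generator with
    euthanasia censoring for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve,
    Matrix,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
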