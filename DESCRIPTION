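Package: boronpk
Title: Population Pharmacokinetics and Bayesian Forecasting of Blood Boron
    for Boron Neutron Capture Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-compartment population pharmacokinetic model of
    L-4-boronophenylalanine (BPA) derived blood boron-10 for boron neutron
    capture therapy (BNCT). Provides closed-form concentration profiles for
    constant-rate intravenous infusions, population simulation with
    log-normal inter-individual variability and a mixed additive plus
    proportional residual-error model, maximum a posteriori (MAP) and Markov
    chain Monte Carlo individual forecasting from sparse blood samples,
    FOCE-I style population estimation with bootstrap and visual predictive
    checks, simulation-based evaluation of sparse blood-sampling schedules
    via prediction-error statistics over the neutron-irradiation window, and
    calibration-based recommendation of neutron irradiation duration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
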