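Package: dalbapop
Title: Population Pharmacokinetics and Dose-Regimen Simulation for
    Long-Interval Dalbavancin Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of dalbavancin in
    patients on long-term suppressive therapy (e.g. ventricular assist device
    driveline infections) and for model-based identification of extended
    dosing intervals. Implements the analytic two-compartment intravenous
    infusion model with superposition over arbitrary multi-cycle regimens,
    nonlinear mixed-effects estimation by stochastic approximation EM (SAEM)
    with log-normal inter-individual variability and below-quantification-limit
    imputation, importance-sampling likelihood and information criteria,
    stepwise covariate search, goodness-of-fit, visual predictive checks,
    nonparametric bootstrap and shrinkage diagnostics, Monte Carlo simulation
    of virtual populations, and probability of target attainment (PTA) and
    cumulative fraction of response (CFR) for fAUC/MIC targets under
    configurable protein-binding scenarios. A synthetic-cohort generator
    emulating the sparse three-sample outpatient sampling design makes every
    pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
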