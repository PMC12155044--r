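Package: serorate
Title: Seroincidence Estimation from Cross-Sectional Antibody Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the rate at which new infections occur in a population
    (seroincidence) from a single cross-sectional quantitative antibody survey.
    Combines a pre-estimated two-phase within-host antibody kinetics model
    (exponential rise to a peak, power-law decay), a constant-rate Poisson
    exposure process, additive biologic noise, multiplicative lognormal
    measurement noise, and interval censoring at the assay quantification
    limits, into a per-observation likelihood that is maximized over the
    log incidence rate. Supports multiple biomarkers (antigen-isotype pairs),
    stratified estimation, Wald and profile-likelihood intervals, and a full
    generative simulator for synthetic serosurveys, parameter-recovery and
    coverage experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
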