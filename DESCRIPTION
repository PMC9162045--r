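Package: cvdtraj
Title: Cardiovascular Risk Trajectories, Dementia Incidence, and Memory
    Decline via Bayesian Multistate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links longitudinal cardiovascular-risk trajectories, measured
    by the office-based Framingham general cardiovascular risk score, to
    dementia incidence and episodic-memory decline in 5-year-wave cohort
    data. Provides a synthetic longitudinal cohort generator with
    multistate transitions and outcome-dependent dropout, per-subject risk
    slope estimation with pattern-mixture adjustment for nonignorable
    dropout, a self-contained Bayesian additive regression trees (BART)
    sampler with continuous and probit outcomes, discrete-time multistate
    (illness-death) survival models with BART transition intensities,
    chained BART imputation of missing risk-factor covariates, and
    Bayesian regression standardization producing group-standardized
    incidence curves, risk ratios, absolute risk reductions, and numbers
    needed to treat.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
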