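Package: pippk
Title: Population Pharmacokinetic Simulation of Piperacillin Target
    Attainment Under Augmented Renal Clearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating piperacillin exposure in critically ill
    patients receiving intermittent intravenous infusions. Implements a
    closed-form two-compartment linear pharmacokinetic model with zero-order
    input and steady-state accumulation, a population model with a creatinine
    clearance covariate on drug clearance, exponential between-subject
    variability and combined residual error, Monte Carlo probability of
    target attainment (PTA) for fT>MIC targets over MIC and creatinine
    clearance grids, cumulative fraction of response (CFR) against MIC
    frequency distributions, a synthetic study-cohort generator, and a
    two-stage population parameter estimator with nonparametric bootstrap
    confidence intervals and a likelihood-ratio covariate test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
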