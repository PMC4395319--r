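Package: idmspec
Title: Systematic Specification of Illness-Death Models Without Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fit, systematically reduce, and evaluate three-state illness-death
    models without recovery under the clock-reset (semi-Markov) formulation.
    Transition-specific Cox proportional hazards with declarative effect
    structures (shared coefficients across transitions, proportional baseline
    hazards via an exp(gamma) progression term, sojourn-time dependence of the
    post-progression death hazard), a step-down model specification procedure
    driven by likelihood-ratio tests and AIC, clock-reset state-probability
    prediction for covariate profiles with a path-microsimulation cross-check,
    and prediction-error-curve evaluation by the IPCW Brier score with the
    0.632+ bootstrap estimator. Includes a Weibull-based cohort simulator
    emulating an ovarian-cancer illness-death process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
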