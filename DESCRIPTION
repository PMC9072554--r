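Package: nrf2dyn
Title: Dynamic Modelling of Nrf2 Pathway Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of the Nrf2-Keap1-p62
    oxidative stress response in liver cells, in two mechanistic variants
    (hinge-latch and dissociation of the Keap1-Nrf2 complex). Provides
    deterministic simulation of electrophile treatments and siRNA
    knock-downs, steady-state constrained parametrisation, alignment of
    biological replicate time courses under a log-normal scaling model,
    maximum-likelihood calibration against fluorescent-reporter, qPCR and
    glutathione observables, profile-likelihood identifiability analysis
    with confidence intervals, a synthetic-data generator for end-to-end
    validation, and PEtab-style import/export of the fitting problem.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
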