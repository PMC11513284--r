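Package: rehabcma
Title: Cost-Minimization Analysis of Mixed Technology-Assisted Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cost-minimization analysis of upper-limb rehabilitation
    services that mix technology-assisted group treatments with conventional
    one-to-one therapy. Implements a deterministic per-cycle cost model with
    linear equipment depreciation and an indirect-cost uplift, elasticity-based
    sensitivity analysis via the Differential Importance Measure, constrained
    optimization of per-cycle savings under gym-capacity and clinical-dose
    constraints, maximum-likelihood fitting of caseload and dose distributions
    with AIC selection, and a capacity-capped Monte-Carlo simulation of the
    probability of achieving given saving levels. Includes a seeded synthetic
    ledger generator emulating the caseload structure of a rehabilitation
    hospital for testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
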