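Package: ckdcdss
Title: Chronic Kidney Disease Clinical Decision Support and Cluster-Trial Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and evaluating an electronic clinical decision
    support system (eCDSS) for chronic kidney disease in primary care, together
    with the machinery of a pragmatic cluster-randomized trial around it:
    synthetic EHR data generation with provider-clustered blood-pressure
    variance, CKD-EPI creatinine and cystatin-C eGFR and the 4-variable kidney
    failure risk equation, EHR-based cohort selection with an exclusion
    cascade, panel-size-balanced cluster randomization, triple-marker risk
    stratification with individualized recommendations and nephrology-referral
    criteria, best-practice-advisory trigger simulation, nephrologist safety
    surveillance rules, implementation-funnel and blood-pressure outcome
    metrics, and the cluster-trial design-effect and power calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
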