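Package: renaltraj
Title: Renal Function Trajectory Analysis for Early Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize longitudinal kidney function in early
    chronic kidney disease: CKD-EPI estimated glomerular filtration rate
    (eGFR) and derived covariates, cohort construction with configurable
    inclusion rules, Bayesian hierarchical mixed-effects estimation of
    per-patient eGFR slopes with posterior-probability classification into
    improved/stable/declining, pattern-mixture group-based latent trajectory
    modeling of subsequent annual-average eGFR with informative-dropout
    adjustment, collapsing of trajectory groups into clinical phenotypes,
    and adjusted mortality and class-membership association models (Cox
    proportional hazards at multiple horizons, multinomial logistic
    regression, interaction tests). Includes a seeded synthetic longitudinal
    cohort generator with latent ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    nnet,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
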