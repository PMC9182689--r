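Package: screenq
Title: Queuing-Network Models for Quantifying Cancer Screening Benefit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact analysis of open networks of infinite-server queues as
    models of cancer screening programs. Solves the traffic equations,
    constructs the product-form (independent Poisson) stationary
    distribution, and derives expected residual lifetime via Little's law.
    Estimates subgroup-level disease parameters from registry-style
    incidence and survival tables (with right-censoring imputation),
    evaluates screening scenarios (detection probability, treatment
    effectiveness, specificity, treatment-associated morbidity and
    mortality), allocates a screening budget greedily across population
    subgroups, and validates the analytic predictions against a
    discrete-event simulator with Kolmogorov-Smirnov goodness-of-fit
    tests of the Poisson predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
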