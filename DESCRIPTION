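Package: dermflow
Title: Cost Comparison and Discrete Event Simulation of Community
    Teledermatology Skin Cancer Referral Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Health-economic evaluation toolkit for urgent suspected skin
    cancer referral services. Compares a community-based store-and-forward
    teledermatology model against face-to-face standard care with an
    activity-based cost comparison (deterministic arm means, incremental
    saving, Welch t test, 1000-iteration probabilistic sensitivity analysis
    and one-way deterministic sensitivity analysis) and a staff-constrained
    discrete event simulation of patient flow (seasonal referral arrivals,
    first-come first-served queueing within staff rota windows, waiting-time
    endpoints from referral to clinical diagnosis, histopathological
    diagnosis and diagnosis communication). Includes a calibration module
    that reconstructs unpublished stage-delay distributions from published
    aggregate waiting times and a synthetic patient cohort generator, so
    every analysis is reproducible without access to patient-level records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
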