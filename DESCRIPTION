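Package: strokepathsim
Title: Clinical Pathway Simulation and Decision Modelling for Stroke
    Thrombolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulation of the emergency stroke thrombolysis
    pathway, per-hospital machine-learning models of thrombolysis
    decision-making, and "what-if" scenario analysis of pathway speed,
    onset-time ascertainment and benchmark decision-making.  Includes a
    synthetic patient-level generator that emulates the statistical
    structure of national stroke-audit data (between-hospital variation in
    pathway speed, onset-known proportion and willingness to treat) so the
    whole pipeline is testable without access to the restricted registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    ranger,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
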