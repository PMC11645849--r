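Package: qalyval
Title: QALY-Based External Validation of Patient-Level Simulation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the global prediction accuracy of
    patient-level (microsimulation) health models using quality-adjusted
    life-years (QALYs) as the outcome. Computes per-participant trial QALYs
    from observed event histories and model QALYs from Monte Carlo
    simulation under annual-cycle accounting with half-cycle correction at
    death, then compares them with five performance metrics: bias, mean
    squared error, mean absolute error, R-squared, and Q-squared (the
    proportional reduction in error, 1 - MSE/SD^2). Includes a
    coefficient-driven annual-cycle microsimulation engine, observed and
    predicted cumulative incidence with death as a competing risk, a
    synthetic trial generator for fully reproducible validation studies,
    and an end-to-end validation pipeline with subgroup and sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cmprsk,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
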