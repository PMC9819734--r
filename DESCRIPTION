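Package: ardrisk
Title: Asbestos-Related Disease Risk Projection from Job-Exposure Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Projects asbestos-related disease burden for occupational
    cohorts from a job-exposure matrix (JEM) of airborne chrysotile fibre
    concentrations. Linear excess-risk models for lung cancer, mesothelioma,
    and gastrointestinal cancer are calibrated against the OSHA asbestos
    cancer-mortality table and applied to cumulative exposures (f/mL-years)
    to predict cancer mortality per 100,000 exposed workers at chosen
    exposure durations; asbestosis incidence is predicted with the linear
    cumulative-dose model Ra = m*f*d. Includes per-1000 significant-risk
    classification against policy thresholds, a seeded lognormal generator
    of synthetic personal exposure measurements for end-to-end pipeline
    testing, and bundled fixtures for the published calibration and
    exposure tables of two Zimbabwean asbestos-cement factories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
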