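Package: flatsig
Title: Left-Flat Sigmoidal Trajectory Models for Regional Brain Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Changepoint regression for staged neurodegeneration. Builds
    CAG-Age Product (CAP) disease-burden scores for Huntington's disease
    mutation carriers and surrogate scores for controls, fits covariate-adjusted
    left-flat sigmoidal trajectories of regional brain volumes (raw or
    whole-brain-normalized) against CAP by profile least squares, compares the
    sigmoid against nested linear and constant models, and estimates the
    changepoint standard deviation and sigmoid-vs-linear p-values by a
    semi-parametric subject-block residual bootstrap. Includes a multi-study
    longitudinal cohort simulator for validation and power exploration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
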