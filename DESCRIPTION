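Package: headgrow
Title: Longitudinal Growth-Trajectory Analysis for Matched Case-Control Infant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for retrospective comparison of head circumference, weight,
    and height growth trajectories between toddlers later diagnosed with autism
    and sex- and birthdate-matched controls. Provides a synthetic matched-cohort
    generator calibrated to the Israeli well-baby visit schedule, per-child
    weekly linear interpolation of irregular measurement series, fitting of a
    three-parameter negative exponential growth model to each child, binned
    group comparisons with Welch t-tests, correlation of head circumference
    with ADOS severity scores, and analytic power computation for two-sample
    designs, together with an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
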