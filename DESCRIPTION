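Package: vfnorm
Title: Construction of Age-Corrected Normative Reference Databases for Static Perimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying age-corrected normative reference
    databases for static automated perimetry on the 24-2 and 10-2 test
    patterns. Covers test-pattern geometry (blind-spot handling, left/right
    eye mirroring, eccentricities), a calibrated synthetic normative cohort
    generator with an age-declining hill of vision and eccentricity-dependent
    skewed pointwise noise, eligibility and reliability quality control with
    retesting and exclusion accounting, pointwise cross-sectional linear age
    regression with nonparametric extreme-percentile reference limits
    (5/2/1/0.5 percent) and order-statistic confidence intervals, derived
    deviation indices (total and pattern deviation, mean deviation, pattern
    standard deviation, foveal deviation) with probability classification,
    and a resampling-based sample-size simulation for extreme-percentile
    reference limits.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
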