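Package: heelgait
Title: Gait-Cycle Variability Analysis of Heel-Worn IMU Recordings for
    Walking-Induced Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse prolonged-walking recordings from a single
    nine-channel inertial measurement unit (IMU) mounted on the posterior
    heel. The package segments recordings into gait cycles from
    medial-lateral angular-velocity peaks, computes ten per-cycle signal
    statistics (median absolute deviation, kurtosis, skewness, root mean
    square, variance, maximum and minimum absolute value, amplitude range,
    median absolute value, and signal power as an energy-consumption proxy)
    for each channel, normalizes window averages to a first-minute baseline
    so every outcome is a unitless ratio, and applies a repeated-measures
    nonparametric battery (Shapiro-Wilk screen, Friedman omnibus, Wilcoxon
    signed-rank post hoc with Bonferroni correction) across baseline,
    30th-minute and 60th-minute windows. A seeded synthetic-gait cohort
    simulator with configurable time-ramped fatigue effects provides ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
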