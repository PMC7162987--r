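Package: vibrotact
Title: Simulation and Test-Retest Reliability Analysis of a Vibrotactile
    Psychophysical Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an eleven-task vibrotactile psychophysical battery
    (reaction time, static and dynamic detection thresholds, amplitude and
    frequency discrimination with and without adaptation, temporal order
    judgement) using transformed up-down adaptive staircases run against
    parametric simulated observers, and implements the complete test-retest
    reliability analysis for such batteries: median-absolute-deviation
    outlier screening, between- and within-subject coefficients of
    variation, two-way absolute-agreement average-measures intraclass
    correlation, Bland-Altman agreement, long-version truncation, and
    random-intercept mixed-effects comparisons with likelihood-ratio tests,
    Tukey contrasts and Holm-Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
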