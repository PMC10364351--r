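Package: tibfrax
Title: Stride Selection, Tibial Strain Summaries, and Probabilistic
    Stress-Fracture Risk for Treadmill Running Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the effect of running stride length on
    tibial stress-fracture risk in cohorts of treadmill runners.
    Implements representative-stride selection from vertical
    ground-reaction-force recordings (threshold segmentation, 100-point
    time normalisation, median-waveform ranking, and a stride-length
    targeted selector for a 10%-reduced condition), CT-derived tissue
    rules for finite-element output tables (modulus-based tissue
    classification, Poisson assignment, 90th-percentile cortical von
    Mises strain), a probabilistic bone fatigue-repair-adaptation model
    of stress-fracture risk under configurable training regimens, and
    the mixed-effects cohort statistics comparing preferred against
    10%-reduced stride lengths across stature groups. A seeded
    synthetic-data module generates cohorts, force traces, element
    tables and outcome tables with the statistical structure the
    analysis assumes, so the full pipeline runs without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
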