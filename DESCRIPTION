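Package: sitpattern
Title: Sitting-Bout Pattern Metrics for Workplace Sedentary-Behaviour Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bout-based analysis of 30-second posture-epoch streams from
    wearable activity monitors: wear-time validation, extraction of sitting,
    standing and light-activity bouts, the summed-squared-sitting-bouts (SSSB)
    statistic with a median-based healthy/unhealthy cutoff, daily subobjective
    and weekly program-goal evaluation, bout-duration profiles, process
    indicators, and stepped-wedge evaluation-plan computations (analyzable
    sample size, Cohen's d precision by simulation, number needed to treat,
    and centering transforms for multilevel analysis). Includes a seeded
    semi-Markov generator of synthetic multi-participant posture streams with
    healthy and unhealthy sitting-pattern presets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
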