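Package: ocuvigor
Title: Saccade Detection, Vigor, and Incentive-Effort Analysis for Eye-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing oculomotor effort in speeded multi-target
    saccade tasks with masked monetary incentives. Simulates task-structured
    gaze recordings with known ground truth, detects saccades with a
    fixed-threshold and a noise-adaptive velocity algorithm, extracts effort
    metrics (target hits, saccade frequency, peak velocity, and main-sequence
    based vigor ratios), scores trial payouts, evaluates subliminal-awareness
    criteria on four-alternative forced-choice data, and runs the
    repeated-measures inferential layer (Greenhouse-Geisser corrected ANOVA
    with a between-subject covariate, Bonferroni post hoc paired comparisons,
    and paired-t power computations).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    minpack.lm,
    car,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
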