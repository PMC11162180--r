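Package: splitgait
Title: Split-Belt Gait Adaptation Behavior and Gait-Cycle Spectral Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing split-belt treadmill adaptation experiments
    at the stride level and in the time-frequency domain. Detects gait events
    from vertical ground-reaction forces, computes step length asymmetry,
    belt symmetry and asymmetric-stride flags, assigns strides to protocol
    subconditions, computes gait-cycle event-related spectral perturbations
    with linear time-warping to a canonical cycle, and tests condition
    contrasts with cluster-based permutation statistics including maximum
    Cohen's d effect sizes and bootstrap confidence intervals. Ships a
    synthetic-session generator that emulates a 2:1 split-belt protocol with
    abrupt and gradual perturbations, an error-driven adaptation model, and
    gait-phase-locked oscillatory bursts, so the whole pipeline is testable
    without laboratory data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
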