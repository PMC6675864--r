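Package: hypnostats
Title: Sleep-Wake Bout Microarchitecture and Transition Heatmaps from Epoch-Scored Hypnograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the microarchitecture of sleep-wake behaviour
    from epoch-scored hypnograms: run-length segmentation into bouts,
    duration-based reclassification of REM sleep, NREM sleep latency scoring
    with an interruption-tolerance rule, per-state time budgets, negative
    binomial regression of bout counts with treatment-to-vehicle frequency
    ratios, log-duration linear models with time-by-treatment interaction
    tests, and transition heatmaps built from standardized residuals of
    bout-succession contingency tables. A semi-Markov hypnogram simulator
    with spike-and-slab dwell mixtures provides fully reproducible synthetic
    studies for testing every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    emmeans,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
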