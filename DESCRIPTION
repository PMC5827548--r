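Package: phasedetect
Title: Phase-Binned Target Detection Analysis for Oscillating
    Transcranial Current Stimulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for masked visual target detection under
    10-Hz oscillating transcranial current stimulation (otCS). Builds
    experiment schedules with a continuous pulse train, runs 3-up/1-down
    adaptive luminance staircases, simulates parametric observers with
    optional phase-locked (entrained) detection, bins detection rates by
    pulse-to-target onset asynchrony into ten 10-ms phase bins, fits
    fixed-frequency sinusoids to standardized bin rates by constrained
    multistart nonlinear least squares, and provides the accompanying
    inferential toolbox: mixed and repeated-measures ANOVA with Mauchly
    sphericity tests and Greenhouse-Geisser correction, paired t and
    Wilcoxon signed-rank tests, Holm adjustment, the JZS default-Cauchy
    Bayes factor, and a Dirichlet-process Bayesian signed-rank test.
    Includes regression-based ocular artifact correction for epoched EEG
    and a simulation harness for type-I error, power and parameter
    recovery of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite,
    rlang,
    withr,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
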