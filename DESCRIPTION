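Package: pupilfreq
Title: Pupil Frequency Tagging Analysis for Binocular Rivalry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decodes the perceptually dominant stimulus in binocular rivalry
    from pupil-size oscillations entrained by sinusoidal luminance modulation
    ("pupil frequency tagging"). Provides pupil-trace cleaning (change-rate
    artifact rejection, blink padding, cubic-spline interpolation, per-block
    z-standardization), chunking of traces into presentation cycles with
    per-cycle complex F1 (modulation-frequency) Fourier components, paired
    tests on the phase-aligned component, per-cycle ROC/AUC percept decoding
    with optimal complex-plane rotation, behavioral dominance statistics
    (repeated-measures ANOVA with generalized eta-squared, sensitivity
    analysis via the noncentral t distribution), and a synthetic-data
    generator that emulates dichoptic luminance-modulated rivalry sessions so
    that the full pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
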