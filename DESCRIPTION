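Package: srbias
Title: Stochastic Resonance Effects on Accuracy and Response Bias in
    Near-Threshold Letter Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a visual psychophysics
    paradigm in which near-threshold letters (consonants C, B, H versus
    vowels O, E, U) are identified in dynamic Gaussian pixel noise under
    unequal (80/20) category base rates. Provides the noise ladder and
    stimulus generator, a QUEST Bayesian adaptive staircase for titrating
    letter luminance to 70% correct, a synthetic threshold-nonlinearity
    observer that exhibits stochastic resonance and prior-induced response
    bias, signal detection theory summaries (accuracy, hit and false-alarm
    rates, d-prime, criterion) with extreme-rate correction, and the
    group-level inference stack: one-way repeated-measures ANOVA, one-tailed
    baseline-referenced post-hoc t-tests with Benjamini-Hochberg FDR
    correction, JZS Bayes factors for one-sample tests and correlations,
    and a priori power analysis via the noncentral t distribution.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    pracma,
    withr
Config/testthat/edition: 3
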