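Package: iortc
Title: Dense-Sampling Analysis of Inhibition-of-Return Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling densely sampled reaction-time time courses
    from exogenous spatial cueing (Posner-style) detection tasks. Simulates
    seeded trial-level experiments over a fine grid of cue-target onset
    asynchronies, screens participants by catch-trial false alarms,
    normalizes reaction times within participants, and derives condition and
    difference time courses with Cousineau-Morey within-subject errors.
    Contrasts non-rhythmic inhibition-of-return accounts (linear or
    exponential-decay inhibitory tagging) against rhythmic attentional
    sampling accounts (bounded-frequency sinusoid) and their hybrid via
    deterministic profiled nonlinear least squares, small-sample-corrected
    information criteria (AICc, BIC), Akaike weights and BIC-approximate
    Bayes factors, per-participant winner tallies, a Greenhouse-Geisser
    corrected repeated-measures ANOVA replication check with generalized eta
    squared, and a max-statistic permutation test on detrended FFT amplitude
    spectra.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
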