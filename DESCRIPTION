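Package: microstatr
Title: Resting-State EEG Microstate Segmentation and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level polarity-invariant modified k-means segmentation of
    resting-state EEG into microstate classes A-D, with global field power
    peak extraction, global explained variance and cross-validation
    diagnostics, template backfitting, temporal metrics (duration,
    occurrence, coverage, transition percentages), normality-routed group
    comparisons with Benjamini-Hochberg correction and effect sizes, and a
    seeded semi-Markov synthetic cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: signal, stats, utils, graphics, grDevices, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
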