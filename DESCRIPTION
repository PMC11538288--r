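Package: holocall
Title: Acoustic Feature Extraction and Taxon Discriminability for Pulsed Fish Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing the pulsed, hand-held calls of holocentrid
    fishes (soldierfishes and squirrelfishes) and similar pulse-train
    vocalizations. Reads and conditions WAV recordings, detects pulses and
    measures the standard temporal and spectral call variables (duration,
    pulse count, pulse period, last-pulse duration, fundamental and dominant
    frequency), applies a threshold rule that segments pulse trains into
    blocks and classifies calls into the P1-P4 pattern groups, summarizes
    sounds per individual with body-size normalization, and quantifies
    taxon-level discriminability through standardized PCA, convex-hull
    acoustic-space occupancy, and discriminant classification with
    correct-classification rates and confusion matrices. A synthetic call
    generator with per-taxon templates provides ground-truth cohorts for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
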