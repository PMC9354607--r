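Package: mfecochg
Title: Multifrequency Intraoperative Electrocochleography Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multifrequency intraoperative
    electrocochleography (ECochG) recorded from a cochlear implant array
    during electrode insertion. Extracts cochlear-microphonic (CM) amplitudes
    from alternating condensation/rarefaction tone-burst epochs via the
    difference curve and cycle-aligned FFT, detects and classifies CM
    amplitude drops along the insertion trajectory, separates intracochlear
    trauma from crossing of the 500-Hz characteristic-frequency place using
    two-frequency synchrony and Greenwood-based cochlear geometry, analyses
    post-insertion electrode sweeps, and reproduces the cohort-level
    statistical program (low-frequency pure-tone-average shifts, univariate
    predictor screening, and the Pearson-Filon comparison of dependent
    correlations). A parametric synthetic-cochlea generator provides
    ground-truthed recordings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
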