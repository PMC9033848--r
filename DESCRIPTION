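Package: frpbp
Title: Cuffless Blood Pressure Estimation from Pulse Waveforms via Fuzzy
    Recurrence Plots and Two-Stream Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts pseudo-periodic photoplethysmogram-like waveforms into
    fuzzy recurrence plots (FRP) through phase-space delay embedding, fuzzy
    c-means clustering and max-min fuzzy-relation composition, and regresses
    systolic and diastolic blood pressure with a two-stream convolutional
    network that fuses the raw 1-D segment with its 2-D FRP. Includes a
    synthetic pulse-waveform generator with blood-pressure-dependent
    morphology, the standard regression metric suite, and device-validation
    grading against the BHS and AAMI standards with Bland-Altman analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
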