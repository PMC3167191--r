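Package: pulsedx
Title: Classification of Deficient and Excess Pulse Qualities from Radial
    Pulse Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine classification of the deficient (Xu Mai) and
    excess (Shi Mai) radial-pulse qualities used in Oriental-medicine pulse
    diagnosis. Implements the full analysis chain for applanation-tonometry
    recordings taken at three palpation positions (Chon, Gwan, Cheok) under
    five stepped hold-down pressures: waveform despiking, baseline-wander
    removal, beat segmentation and ensemble averaging, extraction of the 3 x 5
    pulse-amplitude matrix, pulse-pressure and mean-pulse-amplitude summaries,
    principal-component factor analysis with varimax rotation (plus KMO and
    Bartlett sphericity diagnostics), Fisher's linear discriminant analysis
    with Wilks' Lambda and Box's M, leave-one-out cross-validation, a
    two-stage mixed-variable threshold classifier, and confusion-table
    evaluation by accuracy and the Matthews correlation coefficient. A
    synthetic-cohort generator with known ground truth supports end-to-end
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
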