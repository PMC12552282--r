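Package: ctiq
Title: Objective CT Image Quality, Dose Accounting and Rater Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reference-free objective image-quality analysis for 2D CT
    regions of interest: highpass noise isolation, local standard-deviation
    noise maps, minimum-noise (STDmin) estimation from sliding circular
    regions, histogram-modal signal intensity, SNR and CNR, grey-value
    entropy, and 10-90 percent edge-transition sharpness. Includes a
    digital phantom generator with known ground truth for estimator
    validation, a weight-adapted kV / CTDIvol -> DLP -> effective-dose
    accounting chain for head and neck CT, and Gwet's AC2 chance-corrected
    agreement coefficient for multi-rater ordinal ratings with Fleiss-style
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
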