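Package: dtmkit
Title: Measurement, Reliability and Agreement Analysis for the Wrist
    Dart-Throwing Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the range of the wrist dart-throwing
    motion (DTM) and for validating simple clinical instruments against
    optical motion capture. Computes rigid-body forearm and hand frames
    from a seven-marker cluster, wrist flexion-extension and
    radial-ulnar deviation angles, and the slope, offset and range of
    the oblique DTM plane; scores bubble-inclinometer readings with 5
    degree quantization and trial averaging; estimates inter-rater
    reliability with ICC(2,1) and F-based confidence intervals; and
    performs Bland-Altman agreement analysis with fixed and
    proportional bias detection and ratio-based limits of agreement. A
    seeded synthetic-data module generates marker trajectories and full
    two-rater measurement studies with known ground truth so every
    stage of the pipeline can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
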