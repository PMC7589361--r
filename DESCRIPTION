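Package: posturetrack
Title: Lying-Posture Tracking from a Single Tri-Axial Accelerometer
Version: 0.1.0
Authors@R: person("posturetrack", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Classifies in-bed lying postures (supine, prone, left and right
    lateral) from a single wearable tri-axial accelerometer. Provides episode
    segmentation and normalization, 48 time-domain features with a bagged
    decision-tree ensemble, a bidirectional LSTM sequence classifier trained
    with a length-weighted cross-entropy, a leave-one-subject-out evaluation
    harness with macro metrics and coefficient-of-variation analysis, and a
    seeded simulator of labeled in-bed accelerometer episodes for nine body
    sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
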