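Package: fingertap
Title: Automated Finger-Tapping Assessment from Index-Finger Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects tapping activity blocks and single tap events in raw
    tri-axial index-finger accelerometer recordings of the UPDRS Part III
    Item 3.4 finger-tapping task, extracts clinically relevant kinematic
    features (amplitude, rhythm, decrement), and predicts the expert
    0-4 tapping score with a rule layer plus random-forest classifier.
    Includes the statistical evaluation battery (mean prediction error,
    ICC(3,k), permutation tests, Mann-Whitney condition contrasts, mean
    decrease impurity importance) and a seeded synthetic tapping-signal
    generator with ground truth for fully reproducible testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    randomForest,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
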