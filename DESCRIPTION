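Package: sensoryrisk
Title: Sensor-Stream Monitoring and Fuzzy Sensory-Management
    Recommendations for Classroom Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing 1 Hz multi-sensor classroom sessions
    (environmental, physiological and movement channels) recorded around
    children with atypical sensory processing. Provides session input and
    output, Dunn-quadrant sensory-profile scoring, feature extraction,
    a seeded classroom simulator, entropy/information-gain split selection
    for attention labelling, training and comparison of attention and
    stress classifiers, a three-controller Mamdani fuzzy-logic risk engine
    with largest-of-maximum defuzzification and a strategy catalogue, and
    the evaluation arithmetic for caregiver-teacher report forms, System
    Usability Scale scores, paired t-tests and pooled-SD effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
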