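Package: bovigait
Title: Video-Derived Locomotion Scoring of Dairy Cattle from Keypoint Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores lameness in dairy cows from per-frame 22-keypoint pose
    tracks of a single cow crossing a camera's field of view. Reads
    COCO-style keypoint JSON and a long-format CSV dialect, detects steps
    (swing-to-stance transitions) per hoof, computes three locomotion
    indicators (spine curvature as angle and chord/path ratios, normalized
    head height, same-side inter-hoof distances), aggregates them into
    per-passage features, and assigns a 7-grade locomotion score or a binary
    healthy/lame label through three interchangeable backends: a rule-based
    expert decision tree, classical machine-learning models under
    leave-one-out validation, and a CNN-BiLSTM sequence classifier over the
    per-frame indicator series. A synthetic gait simulator with
    grade-controlled pathology and known ground truth makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    class,
    rpart,
    randomForest,
    e1071,
    xgboost,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
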