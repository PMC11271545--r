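Package: pegtransfer
Title: Automated Assessment of Laparoscopic Peg-Transfer Exercises from
    Object-Detection Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Turns per-frame object and grab detections from recordings of
    the Fundamentals of Laparoscopic Surgery (FLS) peg-transfer exercise
    into an objective assessment: temporal debouncing of boolean state
    timelines with a sliding average, identity tracking and board-geometry
    inference, segmentation into pickup-to-release sessions, detection of
    pitfalls (missed or invalid handovers, invalid pickups and releases),
    duration measurement and pass/fail scoring. Also provides the
    inter-rater agreement statistics used to validate such an assessment
    (percent agreement, unweighted Cohen's kappa, Pearson chi-square,
    paired duration differences) and a scripted exercise simulator that
    renders ground-truth detection streams with configurable detector
    noise (false positives, false negatives, box jitter).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
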