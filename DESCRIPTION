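Package: walkbeat
Title: Sonic Feature Extraction and Gait Analysis for Beat-Synchronized Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how music entrains the speed of
    beat-synchronized walking. Provides a three-level sonic feature extractor
    (frame-level subband loudness and pitch salience, 47 beat-level
    descriptors, and song-level metrical periodicity evidences yielding a
    190-dimensional feature vector per stimulus), wearable-sensor gait metrics
    with metronome-relative speed normalization, pairwise feature
    pre-selection with nested cross-validated subset regression, and
    activating/relaxing extreme-group statistics. Synthetic generators for
    beat-locked audio stimuli, circular-path walking sensor traces,
    planted-model feature datasets and bipolar-adjective ratings make every
    stage testable without access to recorded audio or sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
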