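Package: gazescreen
Title: Eye-Movement Event Detection and Screening Classification for
    Reading Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing binocular gaze recordings of text reading
    as a screening instrument for reading difficulties. Implements a dynamic
    dispersion-threshold state machine that segments 100 Hz binocular
    recordings into fixations, saccades, return sweeps, transients and
    signal distortions; a fixed 168-feature taxonomy summarising
    progressive and regressive fixation and saccade events over horizontal
    and vertical version and vergence signals; linear support-vector
    classification with recursive feature elimination evaluated under
    repeated stratified cross-validation with fold-internal feature
    selection, Y-randomization and random-feature baselines, and the
    variance-corrected resampled t-test; feature selection-frequency
    analysis; and a seeded synthetic-cohort generator emulating silent
    multi-line text reading in high-risk and low-risk reader groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab
Config/testthat/edition: 3
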