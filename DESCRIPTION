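Package: gazecit
Title: Eye-Movement Concealed Information Test Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for eye-movement Concealed Information Tests
    (CIT) with face stimuli: dispersion-threshold (I-DT) fixation parsing of
    raw gaze samples, face interest-area assignment, per-trial markers of
    recognition (fixation counts, interest areas visited, inner-region
    proportions, average fixation durations), virtual-innocent removal
    resampling with within-block z-standardization, and detection-efficiency
    estimation (Cohen's d and Mann-Whitney AUC with bootstrap confidence
    intervals). Includes a seeded synthetic scanpath generator emulating a
    two-condition (standard-guilty vs. fixed-sequence countermeasures)
    single-probe CIT design, plus a-priori power computation and stimulus
    geometry helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
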