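Package: pupilscape
Title: Gaze-Contingent Pupillometry: Scene-Statistic Correlation Maps and
    Pupillary Light Response Analysis
Version: 0.1.0
Authors@R:
    person("Pupilscape", "Developers", email = "pupilscape@example.org",
           role = c("aut", "cre"))
Description: Tools for linking pupil size to dynamic scene statistics in
    gaze-centered coordinates. Provides pupil-trace preprocessing (eye
    selection, iterative velocity-based artifact removal, blink detection
    and repair, anti-aliased downsampling), display gamma fitting and
    RGB-to-luminance / CIELAB transforms, gaze-contingent window extraction
    with off-screen handling, pixel-wise Pearson correlation maps with
    Fisher-Z group inference and Benjamini-Hochberg false discovery rate
    control, dependent-correlation channel comparisons (Williams t, Steiger
    z), an event-locked pupillary light response pipeline (percent signal
    change, trial and subject quality control, peak constriction, two-factor
    repeated-measures ANOVA with Greenhouse-Geisser correction, planned
    difference-score tests), and a synthetic-data generator with known
    ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    farver,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
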