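Package: blinkr
Title: Automated Analysis of Spontaneous Eye Blinking from Eye Aspect
    Ratio Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for objective, video-derived analysis of spontaneous eye
    blinking in facial-palsy clinimetrics. Computes the eye aspect ratio (EAR)
    and palpebral fissure height from per-frame eye landmark tables, detects
    and classifies blink events on high-frame-rate EAR traces with a
    hysteresis threshold relative to a rolling-percentile baseline, reduces
    recordings to per-eye blink summaries and per-minute time courses, and
    assembles side-aligned group comparisons (paired Wilcoxon, one-way ANOVA
    with Bonferroni post-hoc, Spearman correlations against patient-reported
    outcome measures). Includes a seeded synthetic EAR-trace and cohort
    generator emulating healthy, acute-palsy, and postparalytic-synkinesis
    blink profiles so every pipeline stage is testable without patient
    videos, plus a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
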