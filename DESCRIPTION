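Package: blinkscore
Title: Blink Detection and Dry-Eye Screening Scores from Eye Aspect Ratio Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening dry eye disease (DED) from short face videos
    summarised as eye-aspect-ratio (EAR) time series. Computes per-frame EAR
    from six eye landmarks, detects and classifies full and partial blinks with
    either a fixed EAR threshold or a personalised dynamic dual-threshold rule
    derived from the recording's EAR range, converts blink counts into a
    10-point eye healthiness score with DED risk categories, aggregates
    per-participant results into cohort summaries and group comparisons, and
    generates synthetic EAR recordings with known ground-truth blink events for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
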