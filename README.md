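# blinkscore

Screening for dry eye disease (DED) from short face videos summarised as
eye-aspect-ratio (EAR) time series.

DED is the most common ocular-surface disorder and is heavily
under-diagnosed because its clinical tests (tear break-up time, fluorescein
staining) require an office visit. Two behavioural biomarkers are visible
in any one-minute face recording: an elevated blink rate (normal is
15–20/min; > 30/min signals high DED probability) and frequent *partial*
blinks, incomplete closures where the lids never touch. `blinkscore` is the
computational core of such a screen, aimed at people building or validating
video-based blink analysis: it has no video or face-detection code, only
the downstream mathematics, so any landmark detector can feed it.

## What it computes

**Per-frame EAR** from six eye landmarks (temporal/nasal corners
`p1`,`p4`; upper lid `p2`,`p3`; lower lid `p6`,`p5`):

    EAR = (||p2 - p6|| + ||p3 - p5||) / (2 ||p1 - p4||)

≈ 0.25 with eyes open, → 0 at closure; invariant to head pose and camera
distance.

**Blink events** on the EAR series, either with the classical fixed
threshold (EAR ≤ 0.163 for ≥ 3 consecutive frames = one blink) or with
personalised dynamic dual thresholds derived from the recording's own
range,

    T_full    = (0.1281 / 0.27527) (MaxEAR - MinEAR)
    T_partial = 1.4 T_full

segmenting maximal runs at or below `T_partial` and classifying each event
FULL or PARTIAL by whether its minimum reaches `T_full`.

**The 10-point eye healthiness score**: full blinks > 30/min (3 pts),
partial blinks > 5/min (3 pts), dry/gritty feeling (2 pts), woman over 50
(1 pt), regular contact-lens wear (1 pt); totals 0–3 are normal, 4–6 mild
DED (alert), 7–10 severe DED.

**Cohort statistics** (group means, Student/Welch t-tests, score
flagging), with the 20-participant pilot cohort bundled as
`pilot_cohort()`, and a **synthetic EAR generator** with known ground-truth
events for end-to-end validation without any video data.

## Worked example

Simulate a DED-like one-minute recording, run the detection pipeline, and
score the participant:

```r
library(blinkscore)

spec <- ded_profile("ded", seed = 42)       # DED-preset synthetic recording
rec  <- simulate_ear_series(spec)
rep  <- cli_analyze(rec$series, run_config(quiet = TRUE))

rep$summary
#> <ear_summary> AverageEAR 0.2142  MaxEAR 0.2679  MinEAR 0.0031  (1800 frames, 0 missing)
rep$thresholds
#> <threshold_pair> full 0.123219, partial 0.172507 (absolute reference)
rep$metrics
#> <blink_metrics> 54 full (54.0/min), 4 partial (4.0/min) in 60.0 s

q <- questionnaire_record(age = 56, sex = "F",
                          dry_gritty = TRUE, regular_contact_lens = FALSE)
eye_health_report(rep$metrics, q)
#> <eye_health_report> total 6/10 -> MILD_DED [ALERT]
#> <score_breakdown> blink 3 + partial 0 + gritty 2 + woman>50 1 + lens 0 = 6/10

rec$truth$n_full; rec$truth$n_partial     # ground truth: 54 full, 4 partial
```

The detector recovered the generator's 54 full and 4 partial blinks
exactly. The blink rate of 54/min earns 3 points; with the gritty feeling
(2) and the woman-over-50 factor (1) the total of 6 lands in the mild-DED
band and raises the app alert.

Cohort view of the bundled pilot data:

```r
cohort_summary(pilot_cohort())
#> Cohort summary (group means, one-decimal display)
#> group        n    age   full/min   partial/min   score   duration
#> control     10   45.1       22.2           2.5     2.1       61.4
#> ded         10   49.4       37.4           5.8     6.1       61.2
#> Two-sided student t-tests:
#>   full_rate_per_min      t =  -2.667, p = 0.01572
#>   partial_rate_per_min   t =  -1.645, p = 0.1173
#>   eye_score              t =  -4.609, p = 0.0002181
#>   age                    t =  -0.443, p = 0.6631
```

The DED group blinks ~15/min more than controls and scores three times
higher; the eye score separates the groups at p < 0.001.

A thin command-line front-end over the same functions ships at
`inst/cli/blinkscore.R` (`analyze`, `score`, `cohort`, `simulate`
subcommands).

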