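Package: aromamap
Title: Quantifying Psychological Responses to Olfactory Stimuli from EEG and
    Pulse Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating human psychological states during exposure
    to olfactory stimuli (aromas and an unpleasant odor) from two biosignals:
    single-channel frontal EEG and a fingertip photoplethysmogram (PPG).
    Provides ultra-short-term heart-rate-variability valence indexes (pNN50,
    RMSSD) from PPG beat detection, EEG band-power arousal indexes
    (Attention-Meditation surrogate, moving-averaged high-beta/high-alpha
    ratio, delta and theta power), baseline-change normalization against a
    pre-stimulus resting minute, within-subject repeated-measures ANOVA with
    unadjusted post hoc paired comparisons, and arousal-valence emotion maps
    in the style of Russell's circumplex model of affect. A synthetic session
    and cohort generator with controllable stimulus effects makes the whole
    pipeline testable without access to participant recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
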