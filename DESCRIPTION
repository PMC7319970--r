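Package: vocalforage
Title: Vocal Foraging Analysis of Infant-Caregiver Daylong Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analyses infant and caregiver vocalisation sequences from
    day-long, speaker-labelled audio recordings as a foraging process.
    Codes receipt of vocal responses under a 1-second contingency scheme,
    builds vocalisation-to-vocalisation steps in time and in a standardised
    two-dimensional pitch-amplitude space, fits step-size and
    inter-vocalisation-interval distributions by maximum likelihood with
    AIC selection among exponential, normal, lognormal and Pareto families,
    and relates per-recording step statistics to response receipt, infant
    age and sample size with mixed-effects regressions. Includes a
    synthetic-cohort generator with planted, recoverable parameters so the
    full pipeline can be exercised and calibrated without audio data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    e1071,
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
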