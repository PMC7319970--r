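---
title: "Vocal foraging analysis: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocal foraging analysis: models, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalforage)
```

## The problem

Infants learn to vocalise in part through a loop with their caregivers:
a vocalisation sometimes elicits a vocal response from the other party,
and responses shape what gets vocalised next. `vocalforage` treats this
interaction as a *foraging* process. Each speaker is viewed as an agent
moving through a two-dimensional acoustic space — the log mean pitch
(fundamental frequency) and the mean amplitude of each utterance, both
standardised — and through time. The objects of analysis are
**steps**: transitions between two consecutive vocalisations of the same
speaker type, measured as an inter-vocalisation time interval and as
non-directional distances in acoustic space,

$$ s = \sqrt{\Delta f^{2} + \Delta d^{2}}, $$

with $\Delta f$ the absolute change in standardised log pitch and
$\Delta d$ the absolute change in standardised amplitude.

Foraging theory motivates the questions: are step sizes heavy-tailed
(Lévy-walk-like, power-law exponent $1 < \alpha \le 3$), lognormal, or
light-tailed (exponential)? Do steps shrink immediately after a
"resource encounter" — here, the receipt of a vocal response — as in
area-restricted search? And do the dynamics change with infant age?

The package implements the full chain: segment-table I/O, response
coding, step construction, distribution fitting with AIC selection,
and the mixed-effects regression battery, plus a synthetic-cohort
generator with planted parameters so that every stage can be validated
without audio data.

## Input data and preprocessing

The pipeline starts from speaker-labelled segment tables (one CSV per
recording) emulating LENA-derived exports: speaker label (`CHNSP` for
near, clear, speech-related child vocalisations; `CHN_NSP` for other
child vocalisations; `FAN`/`MAN` for female/male adult vocalisations;
anything else becomes `OTHER`), onset/offset in seconds, mean pitch in
Hz and mean amplitude in dB. Events must be non-overlapping with
strictly increasing onsets — the segmentation upstream is mutually
exclusive and exhaustive, so this is a validation contract, not an
assumption.

Conventions fixed in `segments_io`:

* **Unpitched utterances** (no detectable pitch) are removed before any
  analysis, including response coding; the count is retained. Whether
  such events should still block response windows is genuinely
  ambiguous; removing them entirely is the simpler, documented choice.
* **Acoustic standardisation** converts log mean pitch and amplitude to
  z-scores using the pooled mean and *population* (divide-by-n) SD over
  every `CHNSP`, `FAN` and `MAN` event of the whole loaded cohort.
  Non-speech child events are excluded from the pool but still receive
  z-values. Population SD is a deterministic convention; at realistic
  n the difference from the sample SD is negligible.
* **Recorder pauses** delimit *subrecordings*. No response window and
  no step ever crosses a subrecording boundary.

## Response coding (the 1-second contingency scheme)

A vocalisation *receives a response* when the other speaker type starts
vocalising within 1 s of its offset with no intervening same-side
vocalisation. Codes are assigned to `CHNSP` and adult events only:

* **Y** — for an adult event: a `CHNSP` onset in `(offset, offset+1]`
  with no adult onset before it; for a `CHNSP` event: an adult onset in
  the window with no child onset (speech-related or not) before it.
* **NA** — the next same-side onset is ≤ 1 s after the offset with
  nothing from the other side in the gap: one cannot know whether a
  response would have arrived. A Y-qualifying response takes precedence.
* **N** — otherwise.

Boundary conventions are deliberate and tested: the window is half-open
`(offset, offset+1]` (an onset exactly 1 s after the offset counts);
the NA separation uses ≤ 1 s; "intervening" means an onset strictly
inside the gap. Steps inherit the first event's code as their class —
WR ("with response") for Y, WOR ("without response") for N, excluded
for NA. Split (WR vs WOR) analyses additionally retain only steps whose
interval exceeds 1 s, because observing a *non*-response requires a 1-s
wait; the default retention filter is strict (`interval > 1`), with
`interval >= 1` available behind `interval_filter = "ge"` since the
"at least 1 s" phrasing common in this literature can be read either
way.

The coder is validated against an independent exhaustive-scan
implementation (`code_responses_bruteforce()`) on thousands of random
dense sequences, across several window values, with zero tolerated
mismatches.

## Distribution fitting and AIC selection

Step samples (intervals, 2-D steps, per-dimension steps) are fitted by
closed-form maximum likelihood to four families:

| family      | parameters        | MLE |
|-------------|-------------------|-----------------------------|
| exponential | $\lambda$         | $1/\bar{x}$ |
| normal      | $\mu,\sigma$      | mean, population SD |
| lognormal   | $\mu,\sigma$      | mean, population SD of $\ln x$ |
| Pareto      | $x_{min},\alpha$  | $\min x$, $n/\sum \ln(x_i/x_{min})$ |

The Pareto is the power law $P(x) = \alpha x_{min}^\alpha / x^{\alpha+1}$,
$x \ge x_{min}$; with $1 < \alpha \le 3$ it corresponds to a Lévy walk.
Selection is by AIC $= 2k - 2\log L$ with $k = 1$ for the exponential
and $k = 2$ otherwise; $x_{min}$ is counted as a fitted parameter since
it is estimated from the data (set `pareto_k = 1` for the sensitivity
variant). Exact ties are broken by fewer parameters, then by the fixed
family order. Zero-valued steps (identical consecutive acoustics) have
no density under the lognormal or Pareto; they are removed for those
fits and reported in `n_zero`, while exponential and normal fits use
the full sample. The `x_min = min(x)` convention (rather than, e.g., a
Kolmogorov-distance scan over candidate thresholds) is a documented
choice; nothing downstream depends on the alternative.

Fit quality is summarised by a histogram $R^2$: 50 logarithmically
spaced bins spanning the sample range, empirical density
`count/(n * binwidth)` against the fitted pdf at the geometric bin
centres, over occupied bins; fewer than 5 occupied bins yields an
undefined ($NA$) diagnostic. The bin count is configurable; results are
insensitive to it for the sample sizes analysed. Empirical summaries
(median, 90th percentile) always come from the data, never from fits,
using the linear-interpolation quantile convention.

Parameter-level regressions use only recordings whose best-fitting
family equals the *predominant* (modal) family for that
speaker/split/measure cell, so that, e.g., lognormal $\mu$ values are
compared across recordings that are actually lognormal-best.

## Regression battery

All models report *standardized* coefficients: the dependent variable
and continuous predictors are z-scored (population SD) across the
analysis table before fitting; the binary WR/WOR indicator stays 0/1.
(Reports of standardized coefficients rarely state the exact recipe;
this one is fixed and internally consistent — the standardized slope
equals the raw slope times $SD(x)/SD(y)$.)

* `correlate_step_interval()` — per-recording Pearson correlation
  between 2-D acoustic step size and interval, aggregated as mean and
  median r and p per speaker type.
* `lmm_step_vs_interval()` — pooled `s_2d ~ interval + age +
  (1 | infant)`, also on WR-only / WOR-only subsets.
* `lmm_summary_features()` — the central design: per-recording summary
  feature (median, 90th percentile, or a fitted parameter) modelled as
  `dv ~ response + age + sample_size + (1 | infant)`, where
  `sample_size` is the recording's `CHNSP`+`FAN`+`MAN` event count.
  The response × age interaction is excluded by default (available
  behind a flag), as is a variant without the sample-size covariate.
* `glmm_response()` — logistic mixed models of response receipt
  (Y = 1, N = 0, NA excluded) from the vocalisation's standardised
  pitch and amplitude and infant age, optionally adding the
  non-directional preceding-step sizes in pitch, amplitude and time;
  fitted separately for infant-received and adult-received responses.

Linear mixed models are fitted with `lmer` (REML) and
Satterthwaite-approximation p-values via `lmerTest`; logistic models
with `glmer` (Laplace; `nagq` exposed). Method, convergence status,
singular-fit and separation flags are recorded in every output row
rather than silently dropped. Complete separation (e.g. all events
coded Y) is reported as a flag, not an error.

## The synthetic-data generator

The generator is test scaffolding with explicit parameters — there is
no established generative model for such recordings, so nothing here is
a claim about real data. Each recording interleaves two streams:

* **Timing** — each stream is a renewal process: the next onset is the
  previous offset plus an interval drawn from the stream's family.
  Defaults: infant intervals lognormal($\mu$=2.3, $\sigma$=1.6)
  (median ≈ 10 s, ≈ 1,000 speech events per 10-h recording); adult
  intervals Pareto($x_{min}$=0.5, $\alpha$=1.08) — heavy-tailed,
  bursty, with sub-second gaps so the NA rule is exercised. Durations
  are lognormal with means 1.0 s (infant) and 1.5 s (adult).
* **Acoustics** — each stream performs a random walk in an internal
  2-D space, per-dimension step magnitudes lognormal($-0.8$, 0.7) with
  random sign. The walk reflects at ±3 internal units: an unbounded
  walk would drift without limit, which is neither physiological nor
  compatible with a planted response-probability structure under pooled
  z-scoring. Internal coordinates map to raw pitch/amplitude through a
  common slope with speaker-specific baselines (infants ≈ 320 Hz,
  adults ≈ 190 Hz), so pooled z-scores retain realistic speaker offsets.
* **Contingency** — after every vocalisation, a reply by the other
  speaker type is inserted with probability
  `plogis(intercept + b_pitch * f + b_amp * d + b_age * age_std)` at an
  onset uniform in `(0, 1]` s after the offset. Explicit insertion (as
  opposed to thinning a free-running process) makes the planted
  contingency directly recoverable by the 1-s coder. Default
  coefficients mirror the directions reported for real data:
  infant-received `(-1.1, -0.32, +0.17, -0.16)`, adult-received
  `(-1.4, +0.23, +0.45, -0.01)`.
* **Area-restricted search** — when a vocalisation received a reply,
  the *receiving* stream's next interval and acoustic step are
  multiplied by `post_response_interval_scale` (default 0.7) and
  `post_response_acoustic_scale` (default 1).
* **Clutter** — non-speech child events at a low rate (10/h) exercise
  the NA rule; ~2% of events have missing pitch; one 10-min recorder
  pause splits each recording into subrecordings.
* **Ages** — `generate_cohort()` applies monotone log-scale shifts per
  100 days of age to the interval and acoustic-step locations, and the
  per-recording seed is a deterministic hash of (master seed, infant,
  age), so editing one recording of a cohort never perturbs the others.

**Collision semantics.** Streams are scheduled independently, so a new
onset can arrive while the other speaker is still vocalising. The
generator resolves this by *interruption*: the ongoing event is
truncated at the new onset (truncations leaving under 50 ms count as
masked and are dropped). This mirrors mutually exclusive segmentation
of a single audio channel, and it matters for validity: the earlier
design of shifting the new onset past the ongoing event made every
inserted reply physically occupy the seconds after a response, which
lengthened WR intervals specifically and produced a spurious
"response effect" in null data. Under interruption, scheduled onsets
are realised exactly and the null calibrates.

### What the generator does *not* emulate

Real daylong audio has labelling errors, diurnal structure (naps,
meals), multiple simultaneous adults, prosodic content beyond two
summary coordinates, and contingencies at many timescales. Passing
tests on synthetic cohorts therefore demonstrates that the *pipeline*
is correct and calibrated — not that real infant–caregiver data behave
like the generator.

## Validation design and problem sizes

The validation suite (exposed as package functions, reused by the test
suite, `analysis/05_validation.R` and `scripts/acceptance.R`) checks:

1. **Oracle equivalence** — 1,000 random 500-event sequences coded by
   both coders, zero mismatches, and smaller runs at windows 0.5 s and
   2 s.
2. **Fixture** — a 12-event hand-enumerated toy recording covering
   every branch (Y/N/NA, an uncoded non-speech event, the
   window-boundary hit, a sub-1-s interval, the 1-s retention boundary
   and a subrecording break) must reproduce its expected step table
   exactly.
3. **MLE correctness** — closed-form examples exactly; parameter
   recovery within ±0.02 on 10⁵-draw samples.
4. **AIC selection** — ≥ 95/100 correct at n = 5,000 for each family,
   and accuracy non-decreasing from n = 200 to n = 5,000.
5. **End-to-end recovery** — a 60-recording cohort (15 infants ×
   4 ages, 3-h recordings) with planted post-response interval scale
   0.5 and age slope +0.15 yields a negative response β (p < 0.05) on
   infant median interval and a positive age β on infant median
   acoustic step.
6. **Calibration** — 100 null cohorts (8 infants × 2 ages, 1.5-h
   recordings): response/age β's of the summary models and
   pitch/amplitude/age β's of the logistic model reject at 5% in at
   most 15/100 cohorts; same-distribution KS rejects in ≤ 7/100.
7. **Logistic recovery** — with a planted pitch coefficient of −0.5,
   the fitted pitch β is negative in ≥ 95/100 cohorts (4 infants ×
   2 ages, 45-min recordings).
8. **Determinism** — identical configs and seeds produce byte-identical
   output bundles.

Recording lengths and cohort sizes in the suites are scaled-down
choices (hours rather than a full day; the planted effects are large
enough that power is not the constraint); the generator's *defaults*
remain the day-long conditions.

**The calibration null is fully uncoupled.** "No planted effects" is
implemented as: no response insertion at all (logit intercept
→ −∞, so Y codes arise only from chance collisions), scales 1, zero
coefficients, and *memoryless* (exponential, mean 6.75 s) adult
timing. Two subtleties force this design. First, leaving insertion
active with zero coefficients still plants bidirectional turn-taking,
and genuine turn-taking by itself shortens post-response intervals —
a real effect, not a false positive, so it cannot serve as a type-I
null. Second, under heavy-tailed adult timing, chance response codes
are serially dependent and per-recording response rates overdisperse,
which genuinely violates the independence assumptions of the logistic
mixed model (observed inflation up to ~45% for the age term). A type-I
calibration must simulate from the model's null. The flip side is a
documented caveat for real data: with bursty adult vocalisation timing,
the logistic response models' p-values should be interpreted
cautiously, because the same serial dependence is present there.

## Known limitations

* The acoustic space is two summary coordinates per utterance; the
  generator and the analyses inherit that restriction by design.
* The Pareto $x_{min}$ convention and the AIC parameter count for the
  Pareto are documented choices, not recovered facts; both are
  configurable.
* The 1-s window conditions everything; alternative windows are
  supported by `window_s` but the NA rule and retention filter are
  tied to the same constant.
* Interruption semantics truncates durations; durations are therefore
  not a faithful target of analysis in synthetic data (they are not
  analysed anywhere in the pipeline).
* Mixed-model p-values rely on the usual asymptotics; with serially
  dependent response codes (bursty timing) the logistic models are
  anti-conservative, as quantified above.
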