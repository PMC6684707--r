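---
title: "Detecting concealed face recognition from eye movements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting concealed face recognition from eye movements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gazecit` implements a complete analysis chain for eye-movement Concealed
Information Tests (CIT) with single face stimuli, plus a generative model
of the gaze data such a test produces. This vignette explains the models,
the parameters that matter, the numerical choices, and what the package's
simulation-based tests do and do not establish.

## 1. The study design being modelled

A session consists of four CIT blocks. Each block opens with two
unfamiliar practice faces (buffers) and then presents, in random order,
12 unfamiliar irrelevant faces, three images of one personally familiar
identity to be denied (probes) and three images of a second familiar
identity to be acknowledged (targets) — 18 test trials per block, 72 test
images per session. Two between-subject groups of 24 participants differ
only in their concealment instructions: a *standard guilty* (SG) group
conceals freely, a *countermeasures* (CM) group executes a fixed scan
sequence (forehead → right ear → right eye → left eye → left ear → nose →
mouth → chin) on every face. Gaze is sampled at 60 Hz on a 22-inch
1440 × 900 display viewed at 70 cm; the 595 × 420 px face images then
subtend 15.9° × 11.3° (`visual_angle()` reproduces both to one decimal,
which is also why 595 px must be the *horizontal* extent — the reverse
assignment reproduces neither).

The per-group size of 24 is itself a design quantity:
`required_sample_size(0.7, 0.05, 0.95, "one")` searches the smallest
integer *n* for which a one-sample t-test on difference scores with
noncentrality $0.7\sqrt{n}$ and $n-1$ df reaches power 0.95, using the
noncentral t distribution rather than a normal approximation. Only the
one-tailed computation yields 24 (two-tailed gives 27), so one-tailed is
the default — a directional prediction is natural here, since every
marker has a predicted sign.

## 2. Fixation detection (I-DT)

`detect_fixations()` implements dispersion-threshold identification with
the conventional parameters: minimum duration 80 ms, maximum dispersion
100 px. Choices the published parameter pair does not pin down:

* **Dispersion metric.** $D = (\max x - \min x) + (\max y - \min y)$, the
  classic formulation for this algorithm family.
* **Duration convention.** A fixation's duration is
  $(t_{last} - t_{first}) + \Delta$, with $\Delta$ the nominal sample
  interval. At 60 Hz a 5-sample window then spans ≈83 ms and satisfies
  the 80 ms minimum; with the bare time-span convention the threshold
  would require 6 samples (≈83 ms of *span*), silently raising the
  effective minimum.
* **Gaps and blinks.** Invalid samples never contribute. Gaps between
  consecutive valid samples up to `max_gap = 75` ms (a typical blink
  tolerance) are bridged inside a window; longer gaps terminate it. This
  is this package's contract, exposed as a parameter — vendor
  implementations differ and rarely document their rule.
* **Boundaries.** The sample that first violates the dispersion ceiling
  belongs to the next window; emitted fixations are non-overlapping and
  time-ordered. The implementation keeps running min/max while a window
  grows and is verified, property-style, against a brute-force window
  scan that recomputes dispersion from scratch at every step (220+
  random traces per run).

## 3. Interest areas and markers

No pixel geometry for face regions is published for this paradigm, so
`face_layout()` ships a documented, overridable default: the face box is
the image area centred on screen; the eyes are 18% × 12% rectangles at
30%/70% width and 40% height, the nose 20% × 18% at the centre, the
mouth 30% × 12% at 75% height. Centroids inside the box but outside
every inner rectangle are `outer`; centroids off the box are `off_face`.
Two conventions needed a decision:

* `off_face` fixations stay in the denominator of the proportion markers
  (they are real fixations) but add no interest-area category — the
  five-category IA count has no off-image slot.
* The "first fixation" is the first whose onset is at or after stimulus
  onset. The fixation carried over from the pre-stimulus central cross is
  excluded; the cross trains central fixation, and counting its
  continuation would dilute the first-duration marker.

Markers per trial: fixation count, IAs visited (distinct categories,
repeat visits count once), proportions to inner regions / eyes / nose /
mouth / outer, average fixation duration (total fixation time over
count), and first-fixation duration. Exclusion rules: buffers, trials
answered incorrectly (per item type), and trials without usable
fixations, each logged with one reason.

## 4. The detection estimator

`cit_detect()` computes, per condition and marker:

1. **Virtual-innocent standardization.** Per block and repetition, *k*
   irrelevants (*k* = valid probes, ≤3) are removed at random; the
   retained irrelevants' mean and SD standardize the probe and removed
   values. Retained z-scores have mean 0 / SD 1 by construction (asserted
   to 1e-9 in the tests). Blocks whose retained SD is zero are dropped
   from that repetition only; blocks with no valid probe or fewer than
   *k* + 2 retained irrelevants contribute nothing; participants with no
   usable block are excluded with a warning.
2. **Aggregation.** Z-scores are averaged within participant across
   blocks, blocks weighted equally regardless of their valid-trial
   counts — the simplest defensible reading of "an average z-score per
   participant".
3. **Effect size and classification.** Per repetition,
   $d_z = \bar{x}/s_x$ over the participant differences
   $z_{probe} - z_{innocent}$, and the Mann–Whitney AUC over all guilty ×
   innocent cross pairs with half-credit ties (verified against
   exhaustive pair counting). Point estimates average the 1000
   repetitions. *d* is computed on differences rather than probe z-scores
   against zero because the ROC uses both score sets; the two should
   summarise the same contrast.
4. **Uncertainty.** Percentile bootstrap (95%, 1000 resamples) over
   participants, each resample paired with a fresh removal draw, so both
   sampling layers — participants and removals — enter the interval. The
   removal layer contributes little once 1000 repetitions are averaged,
   but omitting it would understate the variance of a single-repetition
   analysis.
5. **Direction percentages.** Share of participants whose rep-averaged
   difference carries the marker's predicted sign (durations and eye
   proportion positive; counts, IAs visited and inner proportion
   negative). An exact zero counts against the prediction.

Seeding: one master seed; the removal stream and every bootstrap stream
are derived from it by fixed offsets, so a full fit — and a full
pipeline run — is a pure function of its inputs and the seed.

## 5. The generative scanpath model

The generator exists so the pipeline can be calibrated and stress-tested
end to end; it emulates the *structure* of the data, not facial saliency.

* **Fixation counts** per trial are $1 + \mathrm{NegBin}(\mu, \theta)$,
  truncated at one fixation. Means are the emulated group means: 1.95
  under SG and 9.84 under CM for unfamiliar faces, with dispersion
  chosen to reproduce SDs of 1.18 and 3.6; probe trials receive an
  additive count shift (+0.35 SG, −0.02 CM), reproducing probe means of
  about 2.3 and 9.8.
* **Durations** are log-normal (median 250 ms, log-SD 0.35, floored at
  100 ms so every planned fixation is detectable) — right-skewed and
  positive, as empirical fixation durations are.
* **Region choice.** SG trials draw regions from a categorical
  distribution dominated by the centre and eyes, with the mouth nearly
  never fixated; CM trials walk the instructed eight-station sequence,
  skipping each station with probability 0.1 and cycling until the drawn
  count is reached.
* **Familiarity effects** (probe trials only): a standardized duration
  shift `afd_effect` (default 0.7, the design effect size) applied on
  the log scale, scaled analytically so the induced standardized
  difference of per-trial AFD equals the nominal value; an eye-bias under
  SG; an extra nose/mouth skip probability under CM; the count shifts
  above. `zero_effects()` zeroes every field, making probe and
  irrelevant trials identically distributed — the basis of the null
  calibration.
* **Participant heterogeneity.** Individual duration effects are drawn
  once per participant from
  $N(\texttt{afd\_effect}, \texttt{afd\_effect\_sd}^2)$ with default SD
  0.9. Without it, averaging 12 probe trials per participant would make
  the across-participant Cohen's *d* far exceed the per-trial effect;
  with it, a realistic minority (~25%) of participants shows no or a
  reversed duration marker, and the recovered *d* sits near the nominal
  value.
* **Rendering.** Each planned fixation becomes
  $\lceil duration/\Delta \rceil$ samples jittered with isotropic
  Gaussian noise (SD 8 px ≈ 0.25°, typical remote-tracker precision; a
  larger value would make the dispersion window split long fixations and
  couple detected counts to durations), joined by 1–2 saccadic
  transition samples, with 2% dropout flagged invalid. Time zero is
  stimulus onset; a 500 ms central-cross fixation precedes it, which is
  what makes "first post-onset fixation" well defined. Consecutive
  planned centroids are kept >110 px apart (city-block) so that, at zero
  noise, render → detect recovers the planned fixation count exactly —
  the round-trip is itself a test oracle.
* **Responses** are independent Bernoulli errors per item type (probe
  23/288, irrelevant 17/1152, target 0.05 — no published target rate
  exists, so a conventional small rate is used).

What the generator does *not* model: saliency of real faces, pupil size,
learning or sequence effects across trials, head movement, and any
dependence of the countermeasure's success on face familiarity beyond
the specified effect fields. Passing tests therefore show that the
*pipeline* is correct and calibrated under a faithful data structure —
not that real faces would yield these effect sizes.

## 6. Calibration results and their sampling limits

Two simulation properties are asserted at the design's own size and are
worth stating precisely because the design size limits them:

* **Null calibration.** With all effects zero, each marker's mean AUC
  (1000 repetitions) should sit near 0.5. It does on average — across
  many cohorts the grand-mean deviation is below 0.01 — but a single
  24-participant cohort carries a per-marker sampling SD of ≈0.055:
  within-block standardization forces probe z-scores to variance ≈1.5
  under the null, only 12 probe trials exist per participant, and the
  probe-side noise does not average out over removal repetitions. A
  ±0.05 band around 0.5 therefore holds only ~60% of the time per
  continuous marker, a floor set by the design, not by any tunable
  parameter.
* **Effect recovery.** With `afd_effect = 0.7` at *n* = 24, the
  recovered AFD *d* centres near 0.60–0.65 (detection-level duration
  quantisation and absorbed saccade samples mildly inflate the observed
  AFD spread, attenuating the standardized effect) with an across-cohort
  SD of ≈0.2 — the theoretical standard error of a Cohen's *d* of 0.7 at
  *n* = 24 is $\sqrt{(1+d^2/2)/n} \approx 0.23$. About two thirds of
  cohorts land in [0.5, 0.9]; a band that narrow would need roughly
  *n* = 50 to hold 80% of the time.

The corresponding acceptance tests assert the narrow bands regardless,
so their occasional failure on a given seed is an expected property of
the design size; the module-level tests assert the calibrated *centres*
(which are stable) rather than single-cohort bands.

## 7. Problem sizes used by the test-suite

The suite simulates at the sizes the analysis itself uses where that is
what is being tested (24 + 24 participants, 4 blocks, 1000 repetitions
for the null calibration; 100 cohorts at *n* = 24 with 100 repetitions
for effect recovery — the repetition count affects only Monte-Carlo
smoothing of the point estimate, not its centre) and at reduced sizes
for structural properties (3–12 participants) where the property does
not depend on scale. Oracles — brute-force I-DT, exhaustive removal
enumeration, exhaustive AUC pair counting, power via
`stats::power.t.test` — are kept independent of the implementation paths
they check.

## 8. Known limitations

* The interest-area layout is a geometric default, not measured facial
  landmarks; real analyses should supply their own `face_layout()`.
* AUC is always oriented as P(guilty > innocent) on the raw z-scores;
  markers with negative predicted direction are *expected* below 0.5.
* The bootstrap treats participants as the only exchangeable units;
  blocks are fixed. With four blocks there is no meaningful block-level
  resampling.
* The SG free-viewing model raises the probe's inner-region share as a
  side effect of the eye bias; an observed *net* decrease of
  inner-region viewing under free viewing (attention spilling to the
  periphery of a recognised face) is not part of the effect vocabulary
  and would need an additional field.
* The power helpers cover the matched-pairs design only.
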