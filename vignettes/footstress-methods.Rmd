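---
title: "Methods: seated stress detection from plantar pressure and ankle motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seated stress detection from plantar pressure and ankle motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footstress)
```

## The measurement model

`footstress` detects acute stress during seated work from two foot-worn
sensors — a 16-channel force-sensitive-resistor insole and a 3-axis
ankle accelerometer, both nominally 50 Hz — exploiting four behavioural
signatures of seated stress: increased forefoot loading, an anterior
shift of the centre of pressure, a change in resting leg posture, and
intermittent foot tapping or leg shaking. The unit of analysis is the
non-overlapping 10 s window; at 50 Hz a complete window holds 500
samples. Every downstream quantity — features, classifier decisions,
the field stress ratio — is defined per window.

The method assumes the wearer is seated (field mode enforces this with
a posture gate), that the insole's sensor geometry is known, and that
streams are essentially gap-free at their nominal rate. Timestamps are
authoritative: windows are defined by time, not sample count, and a
window missing more than 10% of its nominal samples is suppressed
rather than emitted sparse. Streams whose median inter-sample gap
deviates more than 10% from nominal are rejected outright, since a
mis-clocked stream silently corrupts every spectral feature.

## Features

**Pressure (A1–A3).** Channels are smoothed with a 1 s *trailing*
moving average before summing; the window mean of the forefoot sum
(sensors 1–12), rearfoot sum (13–16) and total gives A1, A2, A3. The
filter is causal because the pipeline should behave identically on
recorded files and live streams; the induced ~0.5 s lag is immaterial
against 10 s windows. The filter is *not* applied to accelerometer
channels: the posture means don't need it and the tapping features must
not have their high-frequency content attenuated. A3 is computed as
A1 + A2, which is algebraically the total sum and makes the identity
exact in floating point as well.

**Centre of pressure (B1, B2).** A weighted planar average of the
sensor coordinates with rearfoot sensors up-weighted by
`rear_weight = 3` (implemented exactly as the method defines it; the
factor plausibly compensates the 12-vs-4 sensor count but is taken as
given, and is exposed as a parameter). The CoP is computed from the
window-mean channel values; averaging per-sample CoPs instead is a
genuinely different estimator on time-varying loads, so both are
available (`cop_mode`), with window-mean the default since the feature
definitions are written on per-window pressures. A window whose
weighted total pressure is zero has no defined CoP and is dropped with
a logged reason. Because no numeric sensor coordinates are published
for the reference hardware, the bundled layout
(`inst/extdata/default_layout.yaml`) is a clearly-labelled synthetic
stand-in on a right-foot outline (mm; origin at the posterior-lateral
heel corner); all CoP code takes the layout as an argument so a
measured layout substitutes cleanly.

**Posture (C1–C3).** Raw per-axis window means, in g. Gravity is
deliberately retained — its projection onto the axes *is* the leg-angle
signal.

**Tapping (D1, D2).** Low-amplitude oscillations on one axis can cancel
inside a plain 3D norm when another axis dominates. The axis-inversion
transform reflects one axis about its window maximum
(`a_inv = 2·max(a) − a`, an affine map with slope −1 that preserves
peak-to-peak exactly); three candidate norms are formed, each with one
axis inverted, and the candidate with the largest peak-to-peak (`V3D`)
is kept, ties breaking X→Y→Z. On clean signals this selection can never
lose to the plain norm: inverting an axis that is constant over the
window reproduces the plain norm exactly, so the maximum over
candidates is at least that. With channel noise the comparison can flip
at the 10⁻³ level on windows where tapping rides the gravity-dominated
axis; that is measurement noise, not a property of the transform, so
the property tests assert the inequality on noise-free planted windows.

The spectrum of `V3D` is estimated by mean removal, a rectangular
window and a one-sided periodogram — the plainest estimator, chosen
because the quantities extracted are bin-level summaries, not spectral
densities. D2 (dominant frequency) is the maximum-power bin at or above
`min_freq_hz = 0.5` Hz; the floor excludes DC and postural drift so
"dominant" means tapping, not offset, and is configurable. D1 (median
frequency) is the smallest frequency at which cumulative power over the
searched band reaches half its total — the standard half-power-crossing
definition, adopted because the original description does not formalise
it. Power ties break toward the lower frequency. A window that is
constant after mean removal is flagged and reports (0, 0) by
convention. At 10 s windows the bin width is 0.1 Hz, which bounds the
frequency resolution of both features.

## Ground truth, classifier, validation

Task segments enter training only when the post-task self-rating
(1–7 Likert) agrees with the intended condition: strictly above 4 for
stress tasks, strictly below 4 for relaxation; a rating of exactly 4 is
always ambiguous and excluded, as are unrated tasks. The first and last
60 s of each task are trimmed (accustomisation and exhaustion), so a
task must exceed 120 s to contribute.

The classifier is a two-class Gaussian linear discriminant: class
means, pooled within-class covariance, empirical priors. Features are
z-scored with training-set statistics first — the ten features mix raw
sensor units, millimetres, g and Hz, and without standardisation
multi-feature models are dominated by whichever feature has the largest
scale. (Standardisation is an affine map, so it changes no decision
boundary of an exact LDA; it matters for the ridge term and for
interpretability, and is switchable.) A singular pooled covariance —
collinear features, tiny folds — is ridge-regularised with
λ = 10⁻⁶·mean(diag Σ) and logged. Prediction compares the two linear
discriminant scores; an exact tie resolves to `relax`, the conservative
default for a stress detector. The implementation is cross-checked in
the test suite against both a brute-force Gaussian density-ratio oracle
and an independent reference LDA implementation.

Evaluation is leave-one-user-out: one fold per participant, trained on
all others. Every fold passes a hard provenance assertion that the
training and test participant sets are disjoint — leakage aborts the
run rather than inflating the estimate. Reported are per-user window
accuracies (mean and SD across users, weighting users equally rather
than pooling windows, which matches reporting an SD across users), an
accuracy curve over window position within task, and a two-sided paired
t-test on per-user stressed-fractions under the two conditions
("separation sharpness"). Degenerate pairings are resolved explicitly:
identical pairs give p = 1, a constant nonzero difference gives p = 0
(flagged), fewer than 3 pairs is undefined.

## Field mode

Wrist accelerometry (32 Hz) is cut into 5 s windows and summarised by
the acceleration vector change. The source description names the
feature but not the formula; here

AVC = Σᵢ | ‖vᵢ₊₁‖ − ‖vᵢ‖ | / T  (m s⁻³),

with v the acceleration vector converted from g to m s⁻² by standard
gravity and T the window duration — a first-derivative magnitude over
the entire window, pinned by a finite-difference oracle test and
swappable if a variant is preferred. Thresholds classify walking
(≥ 2 m s⁻³), standing (< 0.1) and sitting ([0.1, 0.2)). The printed
bands leave [0.2, 2) uncovered; those windows get an explicit `unknown`
label and never enter the sitting mask — silently widening a band would
change the published rule. Consecutive sitting windows merge into
intervals, and a 10 s foot window counts as sitting only when fully
contained in one interval (conservative; a partial-overlap mode
exists). Hours are anchored at the stream start; each hour reports its
sitting-window count, stressed count and stress ratio R_S, with
zero-sitting hours flagged undefined and partial trailing hours
flagged. The hourly R_S series is correlated (Pearson, two-sided)
against the self-reported stress level; fewer than 3 valid hours or
zero variance in either series — e.g. a participant reporting the same
level all day — makes the correlation undefined and flagged rather than
an error. EDA summaries (10 s windowed mean and least-squares slope)
are provided as a validation-parity utility only; they feed no
classifier.

## The synthetic generator

Because no recordings are distributable, the generator is first-class,
tested code and defines the study conditions. A laboratory session
follows the standard protocol shape: four 5-minute tasks alternating
stress and relaxation, with condition-consistent Likert ratings drawn
around 5.6 (stress) and 2 (relax) so the ground-truth rule occasionally
excludes a task, as it does in practice. Per user, a baseline is drawn
once: total resting pressure ~N(400, 40) sensor units split roughly
60:40 forefoot:rearfoot with per-sensor jitter, and a resting leg angle
around (0.10, 0.20, 0.95) g with 0.05 g between-user spread — this
heterogeneity is what makes leave-one-user-out a meaningful test.
Stress windows apply four switchable signatures: forefoot gain ×1.5, a
15 mm anterior CoP shift (realised by the gain plus a sum-preserving
linear-in-y tilt of the forefoot pressures, so the planted A1 ratio
stays exact), a +0.3 g shift of the mean Z projection, and 0.05 g
tapping at 4 Hz in 70% of stressed windows, plus white channel noise
(SD 2 sensor units / 0.01 g) everywhere. These magnitudes are generator
choices picked for clear separability at realistic orders of magnitude;
they are not measurements, and `scaled_profile()` interpolates them
toward zero for effect-size sweeps.

A field day plants a deterministic sitting/standing/walking bout
pattern hitting a target sitting fraction (default 79.5%, the realistic
office share), with per-window AVC targets placed inside the respective
bands by scaling a 2 Hz oscillation against the AVC oracle itself.
Within sitting time each 10 s window is stressed with probability equal
to its hour's planted intensity; self-reports follow
SRSL = 1 + round(6·intensity) ± 1 jitter, clipped to 1..7. The jitter
is switchable (`srsl_jitter = FALSE`) so the degenerate flat-reporting
day — all intensities zero, constant SRSL, correlation undefined — is
constructible at any seed.

What the generator does *not* emulate: biomechanics (pressure levels
are stationary within a condition, with no postural micro-adjustments),
sensor drift and saturation, gait dynamics beyond the AVC bands,
between-task carry-over, and EDA physiology beyond the trend sign.
Passing tests therefore demonstrate that the pipeline's arithmetic,
validation logic and statistical behaviour are correct under the
planted model — not that the published accuracy figures transfer to
real participants, which would require the original (undeposited)
recordings.

## Numerical and design choices

* All randomness flows through explicitly seeded Mersenne-Twister
  generators (inversion sampling for normals); generation restores the
  caller's RNG state, and the synth→extract→train→evaluate chain is
  byte-identical across runs with one seed.
* Window segmentation treats each sample as covering 1/rate seconds, so
  a 500-sample stream at 50 Hz spans 10 s and yields exactly one
  window; trailing partials are dropped.
* The effect-size monotonicity check in the acceptance suite holds the
  cohort fixed across effect levels (common random numbers). With
  independently redrawn 5-user cohorts, between-user baseline variation
  moves LOUO accuracy by tens of points between adjacent levels, which
  says something about small-cohort variance, not about the effect;
  the paired design isolates the planted signal.
* Problem sizes in the test suite are chosen to exercise the statistics
  at desk scale: chance calibration uses 5 users × 200 windows × 20
  seeds, the posture and field checks share one 8 h synthetic day, and
  the full suite completes in a few minutes on one core.

## Limitations

The classifier is binary (stress vs relaxation) with no intensity
output; models are population-level, not personalised; only the linear
discriminant is implemented, as the selected classifier of the method;
and the bundled insole geometry is a stand-in, so absolute CoP
coordinates (B1/B2) are only meaningful relative to the layout actually
supplied. Tapping features assume the 3–5 Hz band; slower fidgeting
blends into the drift floor below `min_freq_hz`.
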