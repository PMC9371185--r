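---
title: "Methods: sensor-stream risk assessment for classroom sensory management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-stream risk assessment for classroom sensory management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensoryrisk)
```

`sensoryrisk` models a monitoring loop for children with atypical sensory
processing in classrooms: sense the environment and the child's physiology
at 1 Hz, detect low attention and elevated stress, convert the offending
stimulus and the persistence of the atypical response into a risk
category, and recommend a management strategy. This vignette is the
package's own account of each stage — the procedures, their assumptions,
the tunable parameters, and the choices made where the design was open.

## Sessions, profiles and features

A session is an ordered 1 Hz run of multi-channel samples on an integer,
0-based time grid. Channels can be individually missing and stay `NA`;
nothing is silently zero-filled, because a zero is a legitimate sensor
value on every channel. Gaps in the grid are recorded in a flag table and
never interpolated. The only imputation offered is explicit
last-observation-carried-forward within a session (`impute_locf()`): 1 Hz
physiological signals are locally smooth enough for a one-to-few-second
carry, while carrying across sessions would relate measurements hours or
days apart and is refused by construction.

Sensory-profile scoring follows Dunn's four-quadrant model (low
registration, seeking, sensitivity, avoiding): each quadrant's raw score is
the sum of its Likert items, rescaled by the quadrant's attainable range to
[0, 1]. The real caregiver questionnaire is proprietary, so the
item-to-quadrant map is configuration (`load_profile_map()`); the bundled
20-item instrument (5 items per quadrant, 1–5 Likert) is synthetic and
exercises the scoring mechanics only — it makes no claim about the real
instrument's item counts or polarity.

The detectors use 14 predictors in a fixed order: five environmental
channels, the four normalized quadrant scores, GSR, heart rate, the mean
absolute value of the three accelerometer axes (`(|ax|+|ay|+|az|)/3`,
invariant to axis permutation and sign), and gender (male 0, female 1 — an
encoding the data schema documents because the source protocol lists the
predictor without one) plus age.

## The classroom simulator

The simulator exists so that every downstream module is testable without
recorded child data; its defaults mirror the acquisition protocol it
emulates (35 children, 15 sessions each, ~900 s at 1 Hz, and roughly 42.6%
of sessions carrying assessor labels). Each controlled modality sits at a
regime center — moderate at 400 lx / 26 °C / 60 dB, extremes at 100/750 lx,
15/32 °C, 40/80 dB — with Gaussian jitter of configurable amplitude.

The latent state follows the protocol's labelling scheme exactly when
label noise is zero: relaxing in a moderate regime is low stress, a task in
a moderate regime moderate stress, a task in an extreme regime high
stress. Task accuracy is Beta-distributed (concentration 30) with mean
0.75 in moderate regimes, pulled down under extreme regimes by
`0.10 + 0.25 × sensory-sensitivity`; latent attention is "normal" iff
accuracy exceeds the 0.6 threshold. These anchors put accuracy scores
densely on both sides of the cut, which is what makes the
information-gain recovery of the threshold well-posed. Physiology is
additive: baselines of 200 GSR units, 90 bpm and 0.1 MAV, plus per-level
gains (defaults 40 GSR / 10 bpm / 0.15 MAV per stress step, half-scale
additions for low attention) and per-second Gaussian noise. The magnitudes
are not biophysical claims — no published magnitudes exist for this
protocol — they are chosen once so that the classes are monotonically
separable and the separation degrades smoothly as the gains shrink.

Each session draws its RNG stream from (master seed, child, session
index), so inserting or removing a session never perturbs the others, and
the full generation pipeline is byte-deterministic under a fixed seed. The
simulator does not model session invalidity, assessor disagreement,
sensor drift, or within-session state changes (one latent state per
session); passing tests therefore demonstrate correctness of the
computational pipeline, not field performance on real children.

## Labelling by entropy and information gain

Entropy is Shannon entropy in bits (base 2 — conventional, and the argmax
over thresholds is base-invariant). A threshold split of scores `s` into
`s ≤ t` / `s > t` has gain `H(y) − Σ (n_side/n) H(y_side)`; candidate
thresholds are the midpoints of consecutive distinct sorted scores, a
finite set guaranteed to contain a maximiser. Ties break toward the
smaller threshold — the direction is arbitrary but fixed, and tested. An
all-one-label input is flagged degenerate (gain 0 with a warning) rather
than an error, because it is a legitimate outcome on homogeneous cohorts.
The scheme's undefined (relaxing, extreme) cell is refused with a typed
error instead of being guessed.

## Detection

The comparison protocol is fixed: stratified 80:20 split, stratified
5-fold cross-validated grid search maximising mean CV accuracy, refit on
the full training split, and evaluation on the untouched 20%. Grids (the
source protocol does not publish them) are small and standard: ridge
penalties 1e-1…1e-4 for logistic regression, k ∈ {3, 5, 7, 11} for KNN,
{100, 300} trees × depth {∞, 5, 10} for the random forest, and
{100, 300} rounds × learning rate {0.05, 0.1} × depth {2, 3} for the
boosted trees. The neural network is deliberately not grid-searched: one
hidden layer of 16 units with L2 weight decay 1e-3, matching the source's
"L2 regularization instead of grid search" treatment. KNN and the network
standardise features on training statistics internally; the tree
ensembles are scale-free and see raw features.

F1 is averaged weighted-by-support for the binary attention target and
macro for the 3-class stress target; a class absent from the test set
contributes 0 under macro averaging and is flagged rather than dropped.
Inference time is wall time per sample over enough repeated scoring
passes to total at least 1000 samples — at realistic test sizes a single
pass is timer-noise dominated — and no test asserts absolute timings.
Model selection is argmax accuracy, ties to the faster model, then to a
fixed family order.

Per-sample prediction is the default (each 1 Hz vector scored
independently); a trailing 10 s majority-vote smoother
(`smooth_predictions()`) is available but off by default, since smoothing
trades detection latency for stability and that trade belongs to the
deployment, not the library. An optional grouped split (`group_col`)
assigns whole children to one side, because per-child leakage materially
inflates accuracy when many rows share a child; the default remains the
row-stratified split of the source protocol. Caregiver corrections are
append-only: the corrected row joins the training pool flagged
`source = "caregiver"` and increments the session's wrong-prediction
counter, so retraining never shrinks the training set.

## The fuzzy risk engine

Three independent Mamdani controllers — brightness, temperature, noise —
each take the stimulus, the duration of the atypical response, and the
detected attention and stress. Membership functions are trapezoids and
Gaussians for the continuous inputs and singletons for the categorical
ones; all parameters live in `inst/extdata/fuzzy_config.json` so an
alternative calibration can be dropped in without code changes. The
shipped calibration is a reconstruction — the published curves are not
printed as numbers — chosen so that the canonical exemplars land on their
published terms: 100/400/750 lx read Low/Moderate/High, 15/26/32 °C read
Low/Moderate/High, and 60/70/80 dB read Moderate/Moderate/High (noise has
three overlapping Gaussian terms; 70 dB sits between Moderate and High,
matching its published "moderate-high" reading).

Each controller holds exactly 21 rules, built as a documented grid: three
rules fix moderate-stimulus behaviour (Low Risk at low/moderate stress,
Medium Risk at high stress), and nine per extreme stimulus term escalate
risk with duration and stress, with low attention raising the
short-duration and low-stress cells one band. The two-antecedent forms
"extreme stimulus AND Short duration → Low Risk" and "extreme stimulus AND
Long duration → High Risk" are included verbatim. The grid is monotone by
construction — lengthening the duration or raising stress never lowers the
category — and the test suite verifies this over the crisp input grid.

Inference is standard Mamdani: min conjunction, clipping implication, max
aggregation on a 1001-point grid over the [0, 10] risk universe.
Defuzzification is largest-of-maximum: the largest grid value whose
membership attains the aggregated maximum. The category is the risk term
with maximal membership at the crisp value (band crossings at 3.08 and
6.92), ties resolved toward the higher category — detecting high risk is
the priority, and every tie-break follows it. If no rule fires the
assessment defaults to Low Risk with a logged warning rather than an
error, because a monitoring loop must not die mid-session.

The LOM choice is the engine's central design argument. With a two-term
duration variable whose Short and Long sets overlap, the two verbatim
rules fire together as the duration approaches long; the centroid of the
aggregated bimodal set lands mid-universe ("Medium Risk"), while LOM
commits to the high-risk mode. `defuzz_demo_scenario()` reproduces this
divergence (32 °C, 30 s: both rules at strength 0.25; centroid 5.0 →
Medium, LOM 10 → High). In the full controllers the three-term duration
variable's Short and Long supports are disjoint, so the demonstration
uses its own minimal controller. The bundled 21-combination suite
(`load_defuzz_suite()`) encodes the intended category for crisp prototype
inputs and boundary cases; LOM matches all 21, centroid fewer — its
misses are exactly borderline-stimulus, long-duration, high-stress
combinations where under-calling risk is the costly direction.

Duration itself is tracked by a stated rule (the source leaves it
undefined): the counter increments each second the atypical condition
(attention low OR stress high) holds while the modality's stimulus term is
non-Moderate, and resets to zero when the condition clears. Alerts are
payloads only — built iff the category is High Risk and a subscription is
active — transport is out of scope.

## Evaluation arithmetic

Report-form subscales are sums of 0/1/2 items; the adapted instrument's
item list is configurable with a synthetic 10+10 default. SUS scoring is
the standard normalization (odd items `s − 1`, even `5 − s`, × 2.5), which
is linear, so scoring the item-mean vector of a cohort equals the mean of
per-respondent scores — tested as a property. The effect size divides the
mean change by the pooled SD `sqrt((s₁² + s₂²)/2)`; this reading
reproduces the published effect-size table from its summary means and SDs
to three decimals in seven of eight cases (the eighth recomputes to 0.0645
against a printed 0.065 — inside half a unit of the rounded inputs'
resolution), which we treat as confirmation of the reading. SDs use the
n−1 convention throughout. The paired t-test is the closed form
`mean(d)/(sd(d)/√n)` with a two-tailed Student p; published t values are
not asserted anywhere because they depend on difference-score SDs that
the summary tables do not carry.

## Problem sizes and numerical choices

The test suite and the acceptance script run the simulator at reduced
scale — typically 5–8 children × 6 sessions × 60 s (≈ 400–2900 labelled
rows) for training runs and 40 × 6 for the threshold-recovery check —
sizes at which every property under test (separability, stratification,
recovery, determinism) is already exercised; the defaults of
`simulation_config()` remain the full protocol scale. The output grid's
1001 points give a 0.01 risk resolution; LOM uses a 1e-12 tolerance when
locating the maximum plateau; trapezoid and Gaussian parameters are
validated at construction so evaluation never fails.

## Limitations

The membership parameters and the rule base are reconstructions
constrained by the published exemplars, not the original calibration; the
centroid mismatch fraction on the bundled suite (19/21) is therefore a
property of this reconstruction and is deliberately not asserted against
any published percentage. The simulator's single latent state per session
and additive physiology make detection easier than field data; reported
simulator accuracies validate the pipeline, not clinical performance.
Multiple-testing correction is out of scope (the evaluation design it
mirrors applies none), as are hardware drivers, questionnaire rendering,
and message transport.
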