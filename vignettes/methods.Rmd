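---
title: "Decoding motor imagery from multichannel EEG: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midecode)
```

## The problem

Sensorimotor rhythms — the mu rhythm around 8–13 Hz and the beta rhythm
around 14–30 Hz over central electrodes — desynchronise when a person
executes or imagines a movement. Brain–computer interfaces (BCIs) exploit
this event-related desynchronisation (ERD) to decode motor intent, and a
central design question is how much of the scalp needs to be sampled:
two electrodes over the motor cortex, a standard 19-channel 10–20
montage, or a high-density net with hundreds of channels. `midecode`
implements a complete, tested pipeline for this question: an event-related
study of seven task conditions (move foot/hand `MF`/`MH`, imagine
foot/hand `IF`/`IH`, observe foot/hand `OF`/`OH`, rest `RS`), pairwise
classification of conditions from two feature families — FFT band power
and directed spectral connectivity (ffDTF) — under four montage
densities, with nested cross-validated feature-subset selection and
above-chance significance statistics.

Because no raw clinical EEG ships with the package, a synthetic-study
generator is a first-class module: it produces whole cohorts with the
statistical structure the analysis assumes, with ground truth attached, so
every downstream stage is testable end to end.

## The signal model of the generator

Each recording is, per channel,

* **1/f background**: Gaussian noise spectrally shaped to `1/f^a`
  (default exponent `a = 1`), normalised to unit variance — the scale-free
  backdrop of resting EEG;
* **narrow-band oscillators** on two sensorimotor channel groups (a
  lateral "hand" group around C3/C4 and a midline "foot" group around
  Cz): a mu oscillator (centre 10 Hz, jittered ±0.5 Hz per trial) and a
  beta oscillator (centre 20 Hz), each a sinusoid with a random phase per
  trial and a lognormal amplitude envelope resampled every second
  (sd 0.15 on the log scale, plus a lognormal trial gain of sd 0.05) to
  emulate the waxing and waning of real rhythms;
* **volume conduction**: channels are mixed by a row-normalised
  distance-decaying matrix (`exp(-d^2 / 2(0.25)^2)` over approximate 2-D
  scalp coordinates), so nearby channels see each other's sources;
* optionally, **50 Hz line noise** and **ground-truth directed MVAR
  coupling** injected at named channels for connectivity
  parameter-recovery tests.

Condition effects are multiplicative band-power factors applied to the
oscillators of a channel group. The defaults encode the qualitative
pattern expected of such a study: movement desynchronises strongly and
somatotopically (`MF` acts on the foot group, `MH` on the hand group,
power factors 0.5/0.6 for mu/beta); imagery desynchronises weakly and
diffusely, *identically* for foot and hand (factors 0.75/0.85 on both
groups), so the `IF`–`IH` pair classifies at chance; observation carries
no motor-band effect at all, making `OF`–`OH` a negative control.
Patient-profile recordings shift the reactive mu centre down from 10 to
8 Hz (`patient_peak_shift = 2`), modelling the slowing of cortical
activity after spinal cord injury. No published effect sizes exist for
these factors; they are free parameters of the generator, chosen once so
that planted effects are recoverable by direct band-power estimation at
the study's own scale (25 trials) and that label-permuted data calibrates
at chance — the two properties the test suite asserts.

Generated data is declared already Cz-referenced; no re-referencing
operation exists anywhere, matching an acquisition whose reference
electrode is part of the montage design. The generator does not model
eye-blink or muscle artifacts, pacing-tone auditory potentials, or a
realistic head-model forward projection — so passing tests demonstrate
correctness of the *pipeline* under the assumed band-power structure, not
robustness to artifact-laden clinical data.

Determinism is strict throughout: every operation that draws random
numbers takes a seed, derived seeds are produced by an internal 32-bit
congruential stream, and the same configuration reproduces recordings
bit-identically.

## Preprocessing

The continuous record is high-pass filtered at 1 Hz (4th-order
Butterworth, causal, applied before epoching so filter transients die out
in the lead-in) and optionally notch-filtered at 50 Hz (2nd-order
constant-Q biquad, quality factor 30). There is no artifact rejection by
design — every trial enters the analysis. Epochs of 6 s are cut from each
trial onset and split into six consecutive non-overlapping 1 s
sub-segments ("data augmentation": 25 trials become 150 classification
segments per condition). Sub-segments of one trial are statistically
dependent; the consequence is drawn in the cross-validation design below.

Montages are editable YAML resources: `LD-SM` (C3, C4), `LD-whole` (the
19 standard 10–20 positions, Cz included — the generator produces signal
at Cz since re-referencing is out of scope), `HD-SM` (27 labels over the
central strip), and `HD-whole` (every recorded channel minus a declared
face/neck exclusion list sized to leave 197 of 256). The high-density
label sets are declared approximations of a geodesic sensor layout. At
desk scale (64-channel synthetic recordings) `HD-whole` simply keeps all
64 channels.

## Features

**FFT band power.** Each 250-sample segment at 250 Hz has exactly 1 Hz
bin resolution; the one-sided magnitude-squared spectrum is evaluated at
1–48 Hz with a rectangular window (no taper, no detrending — the data is
already high-passed, and tone power stays in its own bin). Power is then
averaged in 13 bands: 2 Hz bands from 1 to 20 Hz, then 21–30, 31–40 and
41–48 Hz. The printed band edges of such schemes are ambiguous at shared
boundaries; the package assigns `{1,2}, {3,4}, …, {19,20}, {21–30},
{31–40}, {41–48}` so the bands partition the integer bins 1–48, which a
well-defined averaging requires. Features are raw power by default
(`log_power` switches to log10), channel-major, `M × 13` per segment.

**ffDTF connectivity.** Per segment a multivariate autoregressive model
`x(t) = Σ A_k x(t−k) + e(t)` is fitted by a Vieira–Morf lattice
(forward/backward prediction-error partial-correlation recursion) with
unbiased covariance normalisation — every covariance divides by the
actual number of lagged products. Ordinary least squares is kept in the
test suite as an independent oracle; the two agree to < 0.02 on
well-conditioned simulated systems. The transfer function
`H(f) = (I − Σ A_k e^{−i2πfk/fs})^{−1}` is evaluated on the 1–48 Hz
grid and normalised per sink row over sources *and* the whole grid:

$$\eta^2_{ij}(f) = \frac{|H_{ij}(f)|^2}{\sum_{f'} \sum_m |H_{im}(f')|^2},$$

the full-frequency Directed Transfer Function, which emphasises the
frequencies carrying most inflow power and sums to exactly 1 per sink.
The squared-magnitude form is the default (a flag exposes the magnitude
variant, and band aggregation can use bin means — the default — or bin
sums; with sums the normalisation identity survives band averaging, which
the tests exploit). Self-flows (diagonal) are included, giving
`M × M × 13` features.

**Model order.** The coefficient count must stay below the data count:
`N/(M·p) > 1` with `N = 250` samples. The configured orders per montage
are `HD-whole: 1`, `HD-SM: 9`, `LD-whole: 12`, `LD-SM: 50`. The rule's
maximum for 19 channels is 13, and for 2 channels 124; the configured
constants (12 and 50) take precedence — a deliberately high order for the
2-channel montage buys spectral resolution, and the whole-head order is
kept one below the rule's ceiling. `max_model_order()` computes the
rule's bound; the montage resource is authoritative for the pipeline.

## Classification and feature-subset selection

Pairwise linear support-vector machines (soft margin, `C = 1` by
default — the constant is a config parameter, as the original toolbox
default is not documented anywhere) classify seven condition pairs:
`IF–RS`, `IH–RS`, `MF–RS`, `MH–RS`, `IF–IH`, `MF–MH`, and the negative
control `OF–OH`. The decision function is extracted explicitly
(weights + bias) so tests can assert sign symmetries and unbiasedness on
mirror-symmetric data.

Selection runs inside a three-layer nested cross-validation:

1. **Outer 3-fold** split for generalisation. All splits at all layers
   shuffle *trials* (never raw segments), stratified per condition so
   fold sizes differ by at most one trial — the six sub-segments of a
   trial always stay together, otherwise near-duplicate segments would
   leak across the train/test boundary and inflate accuracy.
2. **Middle 5-fold** loop on the outer training set. Each of the five
   runs ranks features by a pooled-variance two-sample t-test (ascending
   p; ties keep column order; zero-variance features get p = 1 and rank
   last) and then greedily grows a feature vector: starting from the top
   feature, each next-ranked candidate is scored by **inner 5-fold**
   cross-validation together with the accepted set and kept only if
   (a) accuracy is at least the best accuracy of all previously accepted
   sets, (b) while the best sensitivity is below 0.75 the sensitivity
   must not drop, and (c) while the best specificity is below 0.5 the
   specificity must strictly improve. The printed description of these
   gates in the source literature is self-contradictory ("had to be ≤"
   where an improvement is plainly intended); the package implements the
   monotone-improvement reading, with the 0.75/0.5 thresholds as config
   constants. The search stops after 30 accepted features, an exhausted
   ranking, or a consecutive-rejection streak exceeding
   `max(⌈0.1·F⌉, 100)` candidates. One inner fold plan is drawn per run
   and reused for every candidate, so candidate scores are comparable
   and the search is deterministic under its seed. Note that the
   greater-or-*equal* acceptance rule (a) admits candidates that tie the
   accuracy, so selections on noise-dominated data drift toward the cap
   rather than staying minimal — a property of the published rule, not a
   defect of the implementation.
3. **Consensus**: features selected in at least 2 of the 5 runs (falling
   back to at least 1 if that is empty); if the result exceeds the mean
   run length, the 31 most frequently selected features are kept, ties
   broken by the better t-test rank. The consensus trains the final SVM
   on the whole outer training set.

Correct counts are pooled over the three outer test folds, so with
25 + 25 trials the total is `N = 300` segments and the per-condition
accuracies (sensitivity/specificity) recombine exactly into the overall
accuracy.

## Above-chance statistics

With balanced classes a trivial majority classifier gets `HC = 150` of
300 right (the maximum-chance criterion — the larger class size). An
observed correct count `H0` is significant when

$$z = \frac{H_0 - H_C}{\sqrt{H_C\,(N - H_C)/N}}$$

exceeds the standard-normal critical value. Two-sided critical values are
the default: at `alpha = 0.05` the smallest significant count is
`H0 = 167` (55.67%), which is only consistent with `z > 1.96`, i.e. the
cumulative two-sided reading of the normal distribution. The
Bonferroni-corrected level for 7 comparisons × 2 feature kinds is
`0.05/14 ≈ 0.0036`, giving a corrected critical count of 176 (58.67%) by
the same computation; published roundings of that corrected count vary
and the package makes no attempt to reproduce any specific one.
Arbitrary class imbalance is supported. Exact binomial or
permutation-based chance levels are deliberately not the default — the
z approximation is the method under study — though the test suite checks
its calibration against binomial simulation.

## Numerical and design notes

* **Fold feasibility.** 25 trials are not divisible by 3 or 5; fold
  sizes differ by at most one trial, assigned by seeded shuffle. The
  3/5/5 nesting needs roughly 12 trials per condition to keep at least
  `k` trials in every layer; the generator default of 25 is comfortable.
* **Lattice degeneracies.** Perfectly collinear channels make the
  residual covariance rank-deficient; the fit stops with an explicit
  error, and `build_ffdtf_features()` drops such segments with a warning
  naming them instead of aborting a whole run.
* **Singular transfer matrices** are reported with the frequency at
  which inversion failed.
* **SVM determinism.** The quadratic-programming solver is deterministic
  given the data; its termination tolerance is exposed for tests that
  need near-exact solutions (e.g. the zero-bias symmetry check).
* **Problem sizes.** The shipped analysis scripts run a 4-recording
  cohort (2 control, 1 patient × 2 sessions) at 43 channels over the two
  low-density montages and both feature kinds — 112 grid cells — which
  reproduces the qualitative pattern of interest (movement pairs well
  above chance, imagery pairs weaker, `IF–IH` and `OF–OH` at chance,
  FFT above ffDTF) at desk scale. The full 22 + 14-recording,
  256-channel profile is expressible through the same `study_config()`
  and montage resources; the 197-channel whole-head grid is
  computationally heavy and intended for batch use, with `run_experiment`
  resumable per cell.
* **What the tests do and do not show.** Green tests certify the
  pipeline's arithmetic (spectra, normalisations, fold algebra, chance
  thresholds), its statistical calibration under the generator's
  assumptions, and recovery of planted effects. They cannot certify
  performance on real clinical EEG, whose artifacts, nonstationarities
  and inter-subject variability the generator intentionally omits.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- study_config(
  n_control_recordings = 1, n_patient_recordings = 0,
  patient_sessions = integer(0), n_channels = 16,
  n_trials_per_condition = 25
)
rec <- generate_recording(cfg, "control", seed = 11)
rec$data <- highpass_filter(rec$data, rec$sampling_rate)
segs <- apply_montage(
  subsegment(segment_trials(rec)),
  load_montages()[["LD-SM"]]
)
ft <- build_fft_features(segs)
out <- nested_classify(ft, segs$condition, segs$trial_id,
  pair = c("MH", "RS"), seed = 5
)
out
chance_criterion(150, out$n, 0.05)
```

On this seed the movement-versus-rest pair classifies 246 of 300 segments
correctly (82%), far above the 167-segment chance threshold, while the
same pipeline on `OF`–`OH` stays below it — the pattern the package
exists to measure.
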