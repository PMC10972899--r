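---
title: "Classifying inter-limb coordination in hands-knees crawling from surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying inter-limb coordination in hands-knees crawling from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hands-knees crawling is a quadrupedal gait: within each crawling cycle —
defined as the interval between two consecutive left-palm touchdowns — the
four limbs (left/right palm, left/right knee) touch down in some order, and
that order is the inter-limb coordination mode (ILCM). The classical
kinematic summary is the ipsilateral phase lag,

$$\mathrm{IPL} = \frac{b}{a} \times 100\,\%,$$

with $a$ the cycle duration and $b$ the lag from left-palm to left-knee
touchdown. IPL near 0/100 % means pace (ipsilateral limbs together), near
50 % trot (diagonal limbs together), near 25/75 % no-limb-pairing (limbs at
quarter-cycle intervals). IPL is, however, a single number: several
genuinely different landing orders share the same left-knee phase, so an
IPL-based taxonomy cannot separate them. Muscle activity can. This package
implements the full pipeline that classifies eight ILCMs from the timing
structure of 30-channel surface-EMG envelopes, plus the gait metrics
(stance/swing durations, duty factor) extracted from a palm pressure
sensor.

`crawlr` is tidyverse-native: user-facing functions take a data frame (or a
cohort/feature tibble) first and return tibbles, matrices live in list
columns, fitted objects have `tidy()`/`glance()` methods, and each result
type has a plotting function.

## The mode catalogue and ideal schedules

Eight modes are fixed by their landing orders; every mode starts with the
event group containing the left palm. Two-group modes place their groups at
phases $\{0, 1/2\}$ of the cycle, four-group modes at
$\{0, 1/4, 1/2, 3/4\}$: uniform spacing is the only assignment consistent
with the catalogue's ideal IPL values (50 % for the trot-lagged modes,
25 %/75 % for the sequential ones, 0 % with a wrap-equivalence to 100 % for
the pace-like mode M1). `ideal_schedule()` realizes any mode as an explicit
touchdown/liftoff table; `compute_ipl()` applied to such a schedule
reproduces the catalogue value exactly, which the tests assert for all
eight modes.

Because IPL lives on a circle (0 ≡ 100), the pace-like mode needs care: a
jittered knee touchdown can land marginally *before* the palm, pushing its
phase to ~99 %. `compute_ipl(wrap = TRUE)` assigns each knee event to its
containing cycle and distances are measured with the circular metric
(`ipl_circular_distance()`). Category assignment (`categorize_ipl()`) is
nearest-ideal over $\{0, 25, 50, 75, 100\}$; exact midpoints are
deterministically broken toward the larger ideal and flagged, so the rule
is symmetric and reproducible.

## Cycle segmentation from the pressure signal

The left palm carries the only contact sensor. Its signal plateaus during
stance and rests at zero during swing, so the first derivative is positive
only while entering stance and negative only while entering swing. Real
derivatives are never exactly zero, so `detect_cycles()`:

1. smooths with a moving average (default 25 ms);
2. thresholds the derivative at a fraction (default 10 %) of its robust
   (99.5th percentile) absolute maximum — making detection invariant to
   positive rescaling of the signal;
3. requires a candidate run to change the smoothed level by at least
   `amp_frac` (default 30 %) of the signal's robust range — sensor noise
   moves the derivative but cannot traverse the plateau amplitude, so this
   rejects spurious crossings that survive smoothing;
4. debounces with a minimum phase duration (default 100 ms) and enforces
   strict stance/swing alternation, trimming incomplete leading/trailing
   phases so the event sequence starts and ends on a stance onset.

Sample indices are 1-based (the native R convention; every consumer of
these indices is R code in this package) and cycles are half-open
`[start, next_start)` intervals, so slicing partitions the signal exactly.
On noiseless synthetic pressure every detected onset lies within the
transition ramp of the true event, and stance + swing durations add up to
the cycle duration to one sample.

## Envelope features

Per cycle and channel the envelope is extracted as: high-pass filter →
demean → full-wave rectify → low-pass filter. Filters are 4th-order
Butterworth applied forward and backward (zero phase), with cutoffs 20 Hz
(high-pass) and 5 Hz (low-pass) — conventional surface-EMG envelope
settings; zero-phase filtering matters because burst *timing* is the
discriminative feature. Each cycle is then resampled to 1000 points by
linear interpolation on a common phase axis and each channel scaled to
unit variance.

Two normalization choices were genuinely open:

* **Order.** Scaling before resampling leaves the final sample's variance
  only approximately one (interpolation perturbs it). The package resamples
  first and scales second, so the delivered 1000 × 30 sample has unit
  channel variance to machine precision; the two orders are otherwise
  equivalent.
* **Scope.** Unit variance is computed per channel *per cycle* (not per
  trial or participant), which makes each sample self-contained — a
  requirement for honest participant-independent evaluation — and makes
  the whole pipeline invariant to per-channel gain (electrode placement,
  skin impedance), which the tests assert.

The guard on minimum cycle length is three low-pass periods (0.6 s at the
5 Hz default): long enough for the filter to settle, short enough to admit
fast crawling cycles.

## Classifiers

Three classifiers operate on the envelope samples:

* **BiLSTM**, implemented from scratch in R (no deep-learning runtime is
  required). The LSTM unit follows the standard gate equations — logistic
  forget/update/output gates, tanh candidate cell — and the bidirectional
  layer runs the sequence forward and time-reversed, concatenating the two
  final hidden states into a head of four dense layers (defaults 256, 128,
  64, then the class layer) with rectifier nonlinearities and a softmax
  output. Training is full backpropagation through time with Adam at the
  reference recipe: learning rate 0.001, β₁ 0.9, β₂ 0.999, ε 1e-8, 128
  hidden units per direction, 60 epochs, batch size ⌈n/10⌉. The analytic
  gradients are verified against numerical differentiation in the test
  suite, and the batched forward pass against a literal scalar evaluation
  of the gate equations. The 1000-point sequence is subsampled to 50 time
  steps before the recurrent layers (the envelope is band-limited to 5 Hz,
  so 50 points per cycle is well above the Nyquist requirement; the full
  sequence adds cost, not information).
* **SVM** (`e1071`), RBF kernel, cost 1, on each channel's envelope
  decimated to 100 points and flattened (3000 dimensions).
* **KNN** (`class`), Euclidean, k = 5, same representation.

All three are deterministic given the training seed; KNN/SVM accuracy is
invariant under any channel permutation applied consistently to training
and test data.

## Evaluation protocols

`run_protocol()` implements three generalization regimes: 3-fold
cross-validation within each participant (participant-specific), 3-fold
over the pooled cohort (multi-participant), and leave-one-participant-out
(participant-independent), each at one speed condition or at "mixed"
(pooled speeds). Folds are stratified by class (and by participant in the
pooled protocol) under a seed-controlled assignment: the reference
procedure does not state its fold construction, and stratification gives
every fold stable per-class coverage. Results carry per-fold accuracies and
a pooled confusion matrix whose row sums equal the per-class test counts; a
`crawl_eval` tidies into per-fold rows and glances into one summary row.
`embed_2d()` provides the t-SNE view of the feature space, and
`analyze_self_selected()` tabulates how cycles recorded under spontaneous
coordination are assigned to the eight modes, per speed, in percent.

## The synthetic cohort generator

The recordings this method was designed for are not publicly available, so
the generator is a first-class, tested module that emulates what the
analysis relies on:

* **Timing.** Per-cycle durations and stance fractions are normal draws per
  speed condition — defaults 3.5 / 2.33 / 1.75 s cycles, and stance
  fractions with means 0.7040 / 0.6497 / 0.5898 and sds 0.0654 / 0.0532 /
  0.0481 at low / medium / fast speed, the stance-share statistics the
  pipeline is expected to recover. Non-palm touchdowns get 50 ms Gaussian
  jitter; a draw that would reorder the mode's event groups is resampled. A
  warm-up cycle (and a full closing cycle) guarantees that every swing
  interval overlapping the observed cycles is defined, so edge cycles are
  not feature-deficient.
* **Pressure.** Plateau during left-palm stance, zero during swing, 50 ms
  linear ramps, additive sensor noise (sd 1 % of the plateau) clipped at
  zero.
* **EMG.** Each of 30 channels is assigned to a limb (8 channels per palm,
  7 per knee — mirroring 15 muscles per body side); a channel's signal is
  band-limited (30–300 Hz) Gaussian noise amplitude-modulated by Gaussian
  bursts centred in its limb's swing phase (burst sd 30 % of the swing
  duration), plus 5 % baseline noise. Modes therefore differ in
  cross-channel burst *timing*, not marginal amplitude — exactly the
  property the envelope features exploit. This is a phenomenological
  model: it does not attempt motor-unit physiology, volume conduction, or
  the inter-muscle synergy structure of real crawling.
* **Participants.** Each virtual participant draws per-channel lognormal
  gains (log-sd 0.3; erased by design by the unit-variance normalization,
  but visible to any analysis of raw signals), per-channel burst-timing
  shifts (sd 12 % of the swing duration), a *coherent per-limb* timing
  offset (sd 15 % of swing) shared by all of a limb's channels, and a
  burst-width multiplier. Shifts are fractions of the swing so timing
  idiosyncrasy scales with cycle period. The limb-level component is what
  makes one participant's activation pattern systematically unlike
  another's: channel-wise noise averages out over a limb's 7–8 channels,
  a coherent offset does not. Its magnitude is calibrated so that
  generalizing to an unseen participant is measurably harder than
  within-participant cross-validation — the protocol ordering the
  evaluation design presupposes — while cross-participant classification
  remains highly accurate.

What passing tests on this cohort do **not** show: robustness to electrode
misplacement, crosstalk, fatigue drift, or real inter-individual synergy
differences. The generator establishes that the pipeline's machinery —
segmentation, normalization, classification, evaluation — is correct and
recovers its own ground truth; claims about real recordings require real
recordings.

## Numerical choices and degenerate inputs

* Zero-variance envelope channels cannot be scaled; they are left at zero
  with a warning rather than producing NaNs.
* A flat pressure signal, a single touchdown, or non-finite samples raise
  errors naming the problem; segmentation never silently returns zero
  cycles.
* IPL category midpoints break toward the larger ideal (flagged); IPL
  means for pace-like data use the circular metric.
* All randomness flows through explicit integer seeds; sub-seeds are
  derived with a fixed linear-congruential scheme kept below $2^{31}$.
  Re-running any stage with the same seed reproduces it bit for bit.
* Problem sizes in the test suite are chosen for desk-scale runs: the
  classification analogue uses the full default cohort (10 participants ×
  8 modes × 15 cycles at low speed, 1200 samples), other properties run on
  2–3 participants with shortened cycles; the recurrent network's
  correctness is tested at small dimensions where numerical
  differentiation is exact, and its training at reduced epoch counts.

## Known limitations

* The BiLSTM trains on CPU in R; at the full reference recipe (128 units,
  60 epochs, 1000-sample cohorts) it is minutes-slow, which is why the
  evaluation grid defaults to the fast classifiers and the network is
  exercised at smoke scale.
* Only the left palm carries a contact sensor, so per-limb stance fractions
  other than the palm's are generator metadata, not measurable outputs —
  matching the instrumentation the method assumes.
* The self-selected-mode emulation draws one spontaneous mode per
  participant and speed from a configurable distribution; it reproduces the
  analysis flow (classify spontaneous cycles with a pooled-trained KNN),
  not any claim about what real adults choose.
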