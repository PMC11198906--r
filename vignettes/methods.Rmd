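---
title: "Two motor cortical beta rhythms: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two motor cortical beta rhythms: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Motor cortical local field potentials (LFPs) in macaques performing
pre-cued reaching often contain not one but two concurrent beta rhythms: a
low band (13–19 Hz, peaking near 16 Hz) dominant in primary motor cortex,
and a high band (23–29 Hz, peaking near 26 Hz) dominant in dorsal premotor
cortex. The two bands behave differently on single trials: the low band's
amplitude tracks movement preparation — it correlates positively with the
upcoming reaction time (RT) and negatively with spontaneous hand postural
micro-movements, with the beta amplitude *lagging* hand velocity by roughly
125 ms — while the high band tracks the temporal structure of the task and
focal visuospatial attention, with larger amplitude when the gaze is on the
work area roughly 240 ms earlier.

`duobeta` implements the full analysis chain needed to establish such a
double dissociation, plus a synthetic session generator that plants every
statistical structure the chain is designed to detect, with a ground-truth
sidecar used as the oracle in the test suite.

## The session model

A session is a directory bundle of continuous records (LFP at 1 kHz, hand
X/Y at 250 Hz, raw eye X/Y at the camera rate), spike trains, a trial table
and site metadata. All times are milliseconds from session start. The task
is a delayed match-to-sample: central touch, 1 s hold, a 300-ms color
selection cue (SEL), then three 300-ms spatial cues (blue–green–pink order)
separated by 1-s delays, and a GO signal 1 s after the third cue. The cue
color named by SEL defines which spatial cue is valid; 3 conditions × 4
positions³ = 192 unique trial types. Analyses align trials to SEL onset and
use the window −1200..5600 ms (6800 samples, 680 ten-millisecond bins).

Continuous signals are stored as Arrow feather files with CSV/JSON
metadata: a fast, typed columnar container with first-class R support,
keeping trials/sites/events as plain CSV.

## The synthetic generator

The generator's defaults define the emulated recording conditions; they are
set once from the study's described phenomenology and are not analysis
knobs:

* **Task**: 40% of initiated trials abort before GO, ~12% are distractor
  errors (the animal reaches to a distractor; the trial's *attended* color
  is then that distractor's), 5% break the target hold. Conditions run in
  blocks of ~15 trials. RTs are lognormal (median ≈ 280 ms, σ_log = 0.12)
  with a +0.1 sd shift per session third (time-on-task).
* **LFP**: 1/f^1.5 background (spectrally shaped Gaussian noise) plus two
  narrow-band carriers at 16 and 26 Hz with slowly drifting frequency.
  Each band's instantaneous amplitude is a piecewise-linear task template
  (high band: high throughout with dips around every spatial cue, deepest
  at the attended one; low band: ramp to a maximum between SEL and the
  attended cue, then a sustained drop; both collapse after GO), multiplied
  by lognormal burst fluctuations (AR(1) log-amplitude, τ = 150 ms,
  σ = 0.6) and by the behavioral couplings below. The low/high mixture of
  a site follows a logistic gradient of its antero-posterior coordinate.
* **Couplings**: low beta × (1 − 0.25·z(hand speed at t−125 ms)); low beta
  × (1 + 0.2·z(RT)) between the attended cue and GO; high beta ×
  (1 + 0.5·centered gaze-In at t−240 ms); both bands × (1 + 0.25·(trial
  position − ½)).
* **Hand**: micro-movements are an Ornstein–Uhlenbeck velocity process
  (τ = 150 ms; σ 0.35 cm/s in X, 0.50 in Y — the Y rail has less friction)
  leak-integrated into a bounded position; the velocity scale rises after
  the attended cue with condition-specific gains. Reaches are minimum-jerk,
  9 cm in 300 ms (peak ≈ 56 cm/s, ~100× the micro-movement scale).
* **Eye**: a fixation walk over the five task positions (center + 4
  targets), between-item points, and out-of-work-area points (base P(out)
  0.40, dropping to 0.12 in attended windows), with 10–40 ms minimum-jerk
  saccadic transitions and OU fixational jitter. The *screen position is an
  exact degree-2 polynomial of the raw camera signal* (coefficients 0.02
  and 0.01 on the quadratic terms, strong enough that uncalibrated cluster
  centers miss targets by > 0.5 cm); the generator inverts that polynomial
  by Newton iteration when emitting raw volts at 240 Hz. Blinks are 80-ms
  plateaus at the saturation bound, restricted to delays.
* **Spikes**: inhomogeneous point processes whose rate is
  `baseline · exp(κ cos(φ − φ₀)) / I₀(κ)` with φ the planted phase of the
  site-dominant band (κ = 0.8, baseline 25 Hz, 2 units/site).

What the generator does *not* emulate: biophysical LFP generation, volume
conduction between sites, saccade main-sequence kinematics, pupil or
heart-rate signals, non-stationary electrode drift, or genuinely
correlated noise across behavioral and neural channels beyond the planted
couplings. Passing tests therefore demonstrate that the analysis chain
recovers the planted structure at realistic SNR — not that real recordings
contain that structure.

## Spectral analysis

Spectrograms use 300-ms Hann windows shifted by 50 ms, zero-padded to a
1-Hz grid (one segment per window), after a zero-phase 4th-order 3-Hz
high-pass; powers are normalized by the site's mean 10–40 Hz power across
trials and windows. The pre-SC1 estimate averages five 500-ms windows with
400-ms overlap over the 900-ms epoch before the first spatial cue,
normalized the same way.

The aperiodic (1/f) component is a straight line in log10-power vs
log10-frequency through two anchors: the last strict local minimum of the
site-average spectrum before 10 Hz and the last before 50 Hz ("strict local
minimum" means below both 1-Hz neighbors). When an anchor is missing the
first point is fixed at 10 Hz and the second at the minimum between 35 and
50 Hz. The line is subtracted from every single-trial log spectrum;
dominance is `(low − high)/(low + high)` on the trial-averaged residuals
over 13–19 vs 23–29 Hz, with a paired t test over per-trial band means.
Negative residual band means in both bands are flagged degenerate rather
than clipped, so pathological fits remain visible.

## Beta envelopes

Band-passing uses the dominant-band edges 16 ± 4 Hz or 26 ± 5 Hz.
An 8th-order Butterworth at these widths is numerically unstable in
transfer-function (b, a) form at 1 kHz, so the zero-phase filter is applied
in the frequency domain using the exact Butterworth magnitude-squared
response (the response `filtfilt` realizes), with reflection padding
against circular edge effects. Amplitude is the modulus of the analytic
signal; each site is z-scored over its whole recording (the first and last
200 ms excluded from the statistics). Sites contribute their dominant band
only when pooling across sites.

## Hand kinematics

Speed is the Euclidean norm of Savitzky–Golay derivatives (order 3) of the
1-kHz upsampled positions. Movement onset searches a 2-s window centered
on GO for speed periods > 6 cm/s lasting > 50 ms and takes the last upward
crossing of 6 cm/s² by the acceleration before the first such period.
Two windows are used: 51 ms for the speed (stable period detection) and
9 ms for the acceleration (a wide window smears the steep reach rise
backwards and biases onsets early by ~15 ms). These windows were chosen to
satisfy the onset-recovery requirement (|error| ≤ 10 ms for ≥ 95% of
planted reaches at default noise) — the threshold values 6 cm/s and
6 cm/s² are fixed.

## Eye processing

Calibration selects likely-fixation samples (2D velocity below the 10th
percentile; when the velocity distribution is degenerate the lowest decile
by rank is used), excludes saturated samples (beyond the 0.5/99.5
percentiles of the raw bounds), and clusters them with k-means for k = 5…8.
Because out-of-area and between-item fixations form diffuse clouds, only
*compact* clusters (mean squared radius within 8× the most compact) are
candidate anchors, and the 5 centers best matching the target geometry
under a least-squares affine map are selected — with a no-flip orientation
constraint, since the square-plus-center layout is otherwise rotationally
ambiguous. A full bivariate degree-2 polynomial per screen coordinate is
fitted on the anchor-cluster samples (samples far from their cluster
center are trimmed first) and applied to the whole trace; the residual at
the cluster centers is reported and is exact (< 1e-6 cm) when the planted
raw-to-screen map is itself degree-2 with no noise. Labels follow the 2-cm
rule around each target, else between/out/saturated, with blink overriding.

Blinks are pairs of velocity-threshold crossings less than 150 ms apart
(500 cm/s at 50 Hz, 800 cm/s at 240 Hz), spanning the gap plus two flanker
samples. Blinks occurring while the gaze is out of the work area are
invisible in the raw signal (the trace already sits at the saturation
bound), so blink recall is evaluated on blinks flanked by in-area gaze.

Saccade detection works on the cumulative 2D speed (path length) of one
trial: runs in the top velocity decile whose path exceeds the reference
displacement are coarse transitions; within each steady period the mean
slope is subtracted and a recursive breakpoint search splits at the sample
maximizing |prior mean − posterior mean| whenever the difference exceeds
the displacement of a reference saccade (10 ms triangular pulse peaking at
60 cm/s, i.e. 0.3 cm of path), with a ±15 ms refractory margin and a 30-ms
minimum window. Steady-period edges adjacent to high-velocity runs are
trimmed by the refractory margin (twice when the run was accepted), since
smoothing leaks saccade tails past the decile cut. Transitions are
classified saccade vs microsaccade by whether the distance between the
isobarycenters of the flanking fixations reaches 0.5 cm.

## Time-resolved statistics

The regressor matrix holds 7 regressors per 10-ms bin: condition (3
levels), reach direction (4 levels), session-z-scored RT, time-on-task
(relative trial position), hand velocity, eye velocity, and gaze In/Out.
Bins with a blink or saturated eye signal are masked per trial; trials
missing a whole signal are dropped everywhere. The model family is every
nonempty regressor subset, plus each subset of ≥ 2 regressors with all its
pairwise interaction columns (dummy-coded products) — 247 models for 7
regressors — scored by the Gaussian BIC `n·log(RSS/n) + k·log(n)` with `k`
counting all coefficients including the intercept. An intercept-only
baseline is scored alongside: without it some regressor is always present
in the winner under null data, contradicting the requirement that null
bins select "no regressor". Ties prefer fewer parameters, then enumeration
order. Note the intercept-only selection rate under the null is governed
by P(χ²₁ > ln n) per cheap regressor, hence n-dependent.

Single-regressor models fit condition across conditions and every other
regressor within condition (per the different per-regressor trial
selections); significance is the model F test, displayed on the 1e-2…1e-8
shading scale. Scramble importance refits the 4-regressor model 100 times
per regressor with that regressor permuted across trials; ΔR² is the full
minus mean permuted R², significant when the full R² beats all 100.

The eq-jpsth is the trials-mean outer cross-product of two trial-aligned
binned signals; 100 trial-pairing shuffles give the correction term, and
division by the square root of the product of the time-resolved
across-trial variances bounds the corrected matrix in [−1, 1]. A cell is
significant when the raw value falls outside all shuffle values (≈ p 0.02
two-sided). Cross-correlograms average the main diagonal ±1 paradiagonal
per lag, split into epochs before/after the attended-cue onset; the
convention `corrected[t_hand, t_beta]` makes a positive most-negative lag
mean beta lagging the hand. The gaze lag scan counts bins (excluding the
first and last 1000 ms of the window) whose envelope differs between gaze
In and Out at p < 0.01 for each lag in −1000..1000 ms (40-ms steps here;
positive lag = gaze leading beta).

Spike–field locking takes the Hilbert phase of the site-dominant band in
the delay before the first spatial cue, requires > 100 spikes, computes
the Rayleigh z, and compares it with 1000 recomputations pairing spike
times with phase segments from other trials; a unit is significant when
its z exceeds at least 95% of the shuffles. At 200 shuffles (the scaled
test condition) the exact level of this rank rule is 11/201 ≈ 5.5%,
measured at 5.7% over 600 independent Poisson units; the acceptance test
uses 400 null units so the Monte-Carlo error of the estimated rate is
small against the ±2-point calibration band.

## Decoding

Features are 50-ms bin means of the envelope over the SEL-aligned window;
trials with > 50% masked samples are dropped, remaining masked cells are
imputed with the trial mean and flagged. The classifier is a random forest
(200 trees, 3 candidate features per split, minimum node size 3, depth cap
80 — the forest hyperparameters reported for the original scikit-learn
grid search, mapped to their `ranger` equivalents; the minimum-samples-
per-split parameter has no direct counterpart and is covered by the node
size) over 20 stratified 60/40 splits with the training classes balanced
by downsampling; the row-normalized confusion matrix is averaged across
splits. The chance bound is the maximum accuracy over 100 label-shuffled
train/test fits. Only unambiguous trials are decoded (no distractor in the
valid cue's position); distractor-error trials (with the two distractors
in different positions) are predicted by a class-balanced model trained on
all unambiguous correct trials, scored against both the attended
(distractor) and the instructed (SEL) labels.

## Problem sizes and reproducibility

The test suite and the acceptance script regenerate everything from code:
typical fixtures are 2 sites × 60–120 trials for recovery checks, 6 sites
× 300 trials for decoding (each band then pools a few hundred trials), 100
synthetic spectra for the aperiodic-estimator ensemble, and 200–400
Poisson units for null calibrations. Every random draw descends from a
single master seed through tagged sub-seeds, so a given seed reproduces
every number bit-for-bit; different seeds give statistically equivalent
results.

## Known limitations

* The two-minima aperiodic estimator assumes the 5–50 Hz background is a
  single power law; a spectral knee inside the range biases the line.
* Band-edge leakage: with bands at 12–20 and 21–31 Hz, broadband bursts
  contribute to both envelopes; the generator's carriers are narrow enough
  that this is negligible, but real data need not be.
* The calibration's compactness filter assumes out-of-area gaze is more
  dispersed than target fixations; a monitor-sized out-of-area cluster
  would defeat it (as it would defeat manual boundary drawing).
* Blink detection cannot see blinks launched from saturated (gaze-out)
  epochs, and the saccade detector's onsets carry the smoothing spread of
  the Savitzky–Golay velocity estimate (a few samples at 240 Hz).
* The BIC scan treats bins independently; no correction for the 680
  simultaneous model selections is attempted (matching the fixed-threshold
  reporting convention), so winner composition should be read as a
  time-resolved description, not as per-bin inference.
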