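---
title: "Methods: activity-driven closed-loop oxygen titration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-driven closed-loop oxygen titration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiflow)
```

## The problem

Patients with COPD on long-term oxygen therapy carry portable oxygen
concentrators whose pulse setting must be raised during exertion and lowered
at rest. In practice patients adjust the device far less often than needed
(`adherence_rate(17, 96)` = `r adherence_rate(17, 96)`% in the motivating
observations), risking exertional desaturation. `actiflow` implements the
software stack of an *intelligent* concentrator: a chest-worn IMU stream is
classified in real time into three activity-intensity classes — sedentary
(0), light (1), moderate (2) — and a lookup-table controller, guarded by a
finite-state machine, maps the class to the pulse setting a physician
pre-titrated for that intensity. Blood oxygen saturation is deliberately
*not* the process variable: oximetry at the wrist is noisy and laggy, while
activity intensity anticipates demand.

## Signal path and its parameters

**Sampling and windowing.** Six channels (3-axis accelerometer in g,
3-axis gyroscope in deg/s) at 25 Hz, cut into non-overlapping 3-s windows
(75 samples). The window label is the majority intensity of its per-sample
activity labels; ties resolve toward the *lower* intensity, the conservative
choice for dosing on ambiguous windows. Trailing partial windows are
dropped.

**DC removal.** Each channel is high-passed by subtracting a first-order
recursive low-pass (cutoff 0.15 Hz, coefficient
$\alpha = \Delta t/(RC+\Delta t)$, $RC = 1/2\pi f_c$), state initialised at
the first sample so a constant input is cancelled from sample one. The whole
continuous recording is filtered once, before windowing, so no filter state
is reset at window boundaries. A known property of this subtract-lowpass
structure at 25 Hz is a small passband loss of roughly $\alpha/2 \approx
1.8\%$ (the one-pole low-pass leaks a little of every frequency); it is
irrelevant for classification, which never compares filtered to unfiltered
amplitudes, but it is why our tests assert 2 Hz retention of $\ge 0.97$
rather than the $0.997$ of the continuous-time idealisation.

**Features.** Exactly 98 time-domain features per window
(`feature_catalog()`), chosen to be cheap on a microcontroller: per-channel
RMS, SD, absolute mean (18); mean of the derivative scaled by $f_s$ (6);
within-sensor Pearson correlations — (ax,ay), (ax,az), (ay,az) and the gyro
triple (6); "simplified energy", defined here as the mean of squares, i.e.
RMS² without any FFT (6); skewness, kurtosis, median (18); min, max, range
(18); IQR with linear-interpolation quantiles (6); signal-magnitude-vector
(per-sample Euclidean norm per sensor) moments (10) and extremes (8); and
the signal magnitude area, the mean of the summed absolute channel values
per sensor (2). Conventions that the source material leaves open and that
we fixed once: correlations are *within* sensor (the only reading giving
exactly 6 of the 15 possible pairs together with a symmetric
accelerometer/gyroscope treatment); skewness is the bias-uncorrected $g_1$;
kurtosis is Pearson (non-excess); zero-variance channels define
correlation/skewness/kurtosis as 0 so that noise-free sedentary fixtures
remain finite. Every feature is verified against an independent loop-based
oracle to $10^{-9}$ relative.

## Feature selection

`wrapper_select()` is a best-first forward search: subsets are scored by
the stratified 5-fold cross-validated accuracy of the wrapped node
classifier itself, the best unexpanded subset is expanded by single-feature
additions (backtracking falls out of the best-first ordering), no subset is
evaluated twice, and the search ends after 5 consecutive non-improving
expansions — the termination the deployed system used. Two numerical
choices: an improvement must exceed $10^{-5}$ accuracy (floating-point
guard), and ties go to the smaller subset, earlier-evaluated first, which
makes the search deterministic given the fold seed.

## The hierarchical classifier

`bhc()` trains two binary nodes arranged as a tree with three leaves:
$\phi_1$ (sedentary vs active) is consulted first; $\phi_2$ (light vs
moderate) only when $\phi_1$ says active. Defaults are the deployed pair: a
gain-ratio univariate threshold tree with pessimistic-error pruning
(C4.5-style behaviour, written in-package because no installed tree offers
gain-ratio splitting with instance weights and error-based pruning) for
$\phi_1$, and weighted LDA — weighted class means, pooled weighted
covariance with a $10^{-6}\cdot\mathrm{tr}(S)/d$ ridge on degeneracy,
weighted priors — for $\phi_2$. $\phi_2$ sees only light/moderate training
windows, re-weighted with `balance_weights()` so both classes carry equal
weight mass ($w_i = N/(K n_c)$), because light windows outnumber stair
windows roughly 5.7:1. Scores are graded (posterior probabilities;
Laplace-smoothed leaf frequencies for the tree) so ROC curves exist per
node.

**Search width.** Running the wrapper over all 98 features inside every
leave-one-subject-out fold multiplies its cost by 18; as the package's
default problem size we pre-rank features with a weighted between/within
variance filter and search the top 24 (`bhc_spec(screen_top = 24)`), which
keeps a full 18-subject LOSO comfortably on one CPU core while leaving the
full-width search available (`screen_top = NULL`). The property tests
exercise `wrapper_select()` directly at full width on small matrices.

## Evaluation

`loso_bhc()` re-runs screening, wrapper selection and node training inside
every fold — the held-out subject contributes nothing to selection — then
pools the held-out predictions over all folds. Reported: one-vs-rest 2×2
confusion matrices and precision/recall/accuracy/F1 per class (percentages
printed to 1 decimal, half-up), a support-weighted summary, pooled
accuracy, the G-metric $\sqrt{Se \cdot Sp}$ where wanted, and one ROC/AUC
per internal node ($\phi_1$ on all windows; $\phi_2$ on the true
light/moderate windows). The trapezoidal AUC is tested to equal exhaustive
Mann–Whitney pair counting with half-weight ties. We enforce that all three
pooled one-vs-rest matrices share one total — the printed reference tables
this design mirrors do not, an inconsistency we deliberately do not
reproduce. No multiclass ROC aggregation is attempted.

## The controller

`therapy_profiles()` is the seven-row lookup table mapping intensity to
pulse setting; every profile is non-decreasing in intensity.
`bolus_volume(setting, bpm)` implements the pulse-dose model at reference
conditions (20 °C, sea level): 180 mL/min per flow setting, hence
$180\cdot\mathrm{setting}/\mathrm{bpm}$ mL per bolus — 12 mL at setting 1
and 15 bpm, 900 mL/min at the top setting.

The safety layer is a Mealy machine (`fsm_state()`, `fsm_step()`): per
classified window the state moves at most one intensity level toward the
observation, and the output is the profile setting of the *new* state. The
exact transition table of the deployed device is not recoverable, so the
single-step rule is our declared interpretation — it is the minimal
mechanism that provably forbids sedentary↔moderate jumps and converges to a
constant observation within two windows. An optional debounce (`debounce =
k`, default 1) requires k consecutive identical observations before
reacting, for classifier chatter. `run_closed_loop()` folds the machine
over a window stream and records settings, adjustment counts and
per-transition latency in windows (3-s units — the controller acts once per
window).

`spo2_summary()` reports CT90/CT85 (percentage of samples below threshold
on a uniform grid), mean and minimum saturation, and desaturation events.
"Event" is not defined in the source material; we count a maximal run below
90% lasting ≥ 10 s, merging runs separated by < 10 s of recovery — both
thresholds configurable.

## The synthetic cohort

No recordings are publicly deposited, so `make_cohort()` generates them.
Per activity segment the model is: a gravity vector (−Y upright, −X lying —
the lying orientation is our choice; the axis convention Y-to-head,
Z-along-walk is the device's) tilted by a small per-posture offset, plus,
for locomotion, two harmonics at the cadence and twice the cadence on the
gait axes with matched gyro oscillation, plus white Gaussian noise per
channel. Stairs scale the gait amplitudes by the subject's
`stair_amp_scale` and replace the second harmonic with a fixed-phase cosine
term, giving the vertical channel a positive, roughly amplitude-invariant
skewness (the sharp heel-strike asymmetry of stair negotiation); since the
cosine term is orthogonal to the fundamental, the vertical RMS still scales
exactly with `stair_amp_scale`, which the tests exploit. A slow 0.35 Hz
pitch sway is added on the pitch gyro during stairs. Cohort defaults mirror
the study conditions: 18 subjects; 3 min seated rest, a 12-min circuit of
six laps (102 s walking + 9 s up + 9 s down, light:moderate exposure
≈ 5.7:1, matching the reported class balance), optional seated stops of
20–40 s (probability 0.25 per lap — chairs were available on the real
route), 3 min seated rest. Subject parameters are drawn from ranges
plausible for elderly COPD patients (cadence 1.5–2.1 Hz, step amplitude
0.15–0.30 g, stair factor 1.3–1.7, MEMS-grade noise); the source reports no
amplitude statistics, so these are modelling choices fixed once, not
calibrated claims. Per-subject seeds derive from the cohort seed, so
cohorts are reproducible subject by subject.

**What the generator does and does not show.** It makes the feature
families class-discriminative in the way real gait is (amplitude separates
sedentary from locomotion; waveform asymmetry separates stairs from level
walking) and it reproduces the study's class imbalance and protocol
timing. It is not biomechanically realistic: no double-support timing, no
turning, no inter-step variability beyond white noise, no barometer (the
real device's pressure channel was not used either), and no SpO₂ coupled
to activity (no model for it exists in the source). Passing the recovery
tests therefore demonstrates that the pipeline — filtering, features,
selection, hierarchical training, LOSO bookkeeping, FSM — is implemented
correctly and can recover a planted class structure across subjects; it
does not certify accuracy on real patients.

## Problem sizes used by the test-suite

The worked-example tests are instantaneous (they recompute printed table
cells). The parameter-recovery test runs a full 18-subject LOSO —
selection re-run per fold over the top-24 pool, tree + LDA nodes — on one
core; the remaining property suites use matrices of tens of columns and a
few hundred rows. Degenerate-input behaviour (zero-variance features,
collinear LDA inputs, empty streams, single-class labels) is error-checked
explicitly rather than left to downstream NaNs.

## Known limitations

- The FSM transition rule and the desaturation-event definition are
  declared interpretations of an under-specified mechanism.
- Wrapper selection under the default screen is not identical to a
  full-width search; with strongly redundant features both reach the same
  CV accuracy but may pick different representatives.
- Reported subset sizes and per-algorithm comparisons from the original
  patient data are not reproducible by construction (the data were never
  deposited); only the metric *formulas* are pinned to printed values.
- SVM / MLP / RBF nodes are supported only through the plug-in node
  contract, mirroring the fact that the deployed device used only the
  tree + LDA pair.
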