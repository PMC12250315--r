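---
title: "Short-horizon neonatal seizure forecasting: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-horizon neonatal seizure forecasting: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seizecast` implements a complete short-horizon seizure-forecasting
pipeline for neonatal EEG. This vignette explains the science behind
each stage, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the design
decisions taken where the methodology was genuinely open.

## The forecasting problem

Neonatal seizures are frequent in the ICU, mostly subclinical, and
currently addressed by detection after onset. Forecasting asks whether
the minutes before a seizure carry an EEG signature strong enough to
warn ahead of time. The operational form of the question is fixed by
two horizons: the **seizure prediction horizon** (SPH), the minimum
lead time between an alarm and the period in which the seizure is
expected (the window available for intervention), and the **seizure
occurrence period** (SOP), the window after the SPH during which the
predicted seizure should occur. An alarm raised at time $t$ is a true
positive iff a seizure onsets within $[t + \mathrm{SPH},
t + \mathrm{SPH} + \mathrm{SOP})$.

## Preprocessing and epoch-state labeling

Raw referential EEG is reduced to a longitudinal bipolar montage
(anode minus cathode per derivation), band-pass filtered to
0.1–20 Hz — electromyogenic and electrical artifacts dominate neonatal
ICU acquisition above 20 Hz — and resampled to 40 Hz. The band-pass is
realized as separate 4th-order Butterworth low-pass and high-pass
filters applied forward–backward (`signal::filtfilt`), because an
8-pole band-pass with a 0.1 Hz edge is numerically fragile at typical
acquisition rates while the cascade is stable; zero-phase filtering
matters because phase distortion would shift preictal timing. Both
operations are linear, so montage derivation and filtering commute (a
property the test suite checks).

The timeline is segmented into non-overlapping 20-s epochs. Epochs
overlapping a seizure are *ictal*; epochs fully inside
$[\text{onset} - 360\,\mathrm{s}, \text{onset} - 60\,\mathrm{s})$ are
*preictal*; epochs fully between 60 s after a seizure offset and 360 s
before the next onset are *interictal*; everything else is *excluded*.
Three conventions deserve notice:

* The classical interictal definition ends 5 min before the next
  seizure while the preictal window opens 6 min before, leaving minute
  6→5 claimed by both. We give the preictal class precedence and end
  interictal 6 min before onset, keeping the classes disjoint:
  contaminating the negative class with near-onset data is the
  costlier error.
* Epochs that straddle a state boundary are excluded rather than
  majority-labeled, keeping the test surface unambiguous.
* When two seizures fall 280–300 s apart their preictal windows
  overlap by less than one epoch; windows are unioned before the
  containment test, so an epoch every second of which lies 6–1 min
  before *some* onset is preictal. This matches the per-second
  semantics the label oracle uses.

Epochs whose look-ahead window $[\text{end}, \text{end} + \mathrm{SPH}
+ \mathrm{SOP})$ runs past the end of the recording without an
intervening onset are right-censored (outcome unknowable) and
excluded. Seizures closer together than the SPH are merged into a
single event before labeling and scoring.

## QEEG features

Per epoch and derivation, three families (all parameters exposed in
`feature_spec()`):

1. **Asymmetry indices of summary statistics.** For each homologous
   left/right derivation pair and each of mean, population SD, excess
   kurtosis, skewness, and the 10th/90th percentiles (linear
   interpolation), the bounded, scale-free, antisymmetric index
   $(L - R)/(|L| + |R| + \delta)$ with $\delta = 10^{-12}$ guarding
   the zero denominator. Constant signals define skew/kurtosis as 0
   (flagged), never NaN.
2. **Band powers.** Welch periodograms (4-s Hann segments, 50 %
   overlap) integrated over δ (0.5–4), θ (4–8), α (8–13) and β
   (13–20 Hz) — the conventional bands truncated at the filter edge —
   in both log-absolute and relative form; relative powers divide by
   total 0.5–20 Hz power, so the tiling bands sum to one exactly.
3. **Recurrence quantification analysis.** The signal is decimated ×2,
   time-delay embedded with $m = 3$, $\tau = 1$, and thresholded at
   $\varepsilon = 0.2\,\mathrm{SD}$; the main diagonal is excluded
   (Theiler window 1). Reported: recurrence rate, determinism and
   laminarity (diagonal/vertical lines of length ≥ 2), and mean
   diagonal line length. These are standard RQA defaults for short
   physiological epochs; a constant epoch returns RR = DET = LAM = 1
   by convention, flagged.

The default montage for the 8-electrode synthetic layout yields
4 × 6 asymmetry + 8 × 8 spectral + 8 × 4 RQA = 120 features. Left-right
channel transposition negates the asymmetry columns and permutes the
per-channel columns — an exact identity the package exploits to
augment training data at the feature level instead of re-running
signal processing, with a test proving the two routes equal.

## The sequence forecaster

Rolling windows of $T = 15$ consecutive epochs (5 min, matching the
preictal span) ending at the labeled epoch feed a ConvLSTM: two
temporal convolution blocks (kernel 3, same padding, ReLU) over the
feature sequence, one LSTM layer, dropout 0.2 on the final hidden
state, and a sigmoid head, trained with Adam (learning rate $10^{-3}$)
on binary cross-entropy with inverse-prevalence class weights, early
stopping on validation loss (patience 4). The default widths are
conv 16/32 with hidden size 32 — sized so that a full 10-fold
cross-validation of the default cohort trains in a few minutes on one
CPU; they are package defaults, not an architectural claim, and are
exposed in `train_config()` alongside a plugin contract (`fit`/`predict`
functions) through which alternative sequence models or classical
baselines run on identical interfaces. A ridge-logistic baseline on
the flattened window ships as `arch = "logistic"`. Forward and
backward passes are written directly in vectorized base R; the
backward pass is verified against numerical differentiation to
$10^{-5}$ relative error in the test suite.

Evaluation uses nested subject-stratified 10-fold cross-validation:
subjects (stratified on the has-seizure flag) are partitioned into ten
disjoint test splits; within each fold the remaining subjects split
into training (67.5 % of subjects) and validation (22.5 %) used only
for early stopping and operating-point selection. Feature
standardization is fit on training windows only; augmentation applies
to training folds only and augmented copies inherit their parent
subject's assignment. Every fold's subject usage is recorded and
`check_leakage()` verifies that no test subject's data touched
training, standardization or augmentation.

## Alarm system and its metrics

A warning is issued when the predicted preictal probability crosses a
threshold; the alarm stays active for SPH + SOP (the alarm warning
period) and re-triggering during an active warning is suppressed, the
next trigger being eligible at the first epoch after expiry — the
standard one-alarm-at-a-time convention. All time-based metrics are
counted on the 20-s epoch grid.

* **Time-point sensitivity** (after Proix): time points in true alarms
  divided by all time points in alarm states associated with seizures.
  For a missed seizure the denominator receives the trigger-eligible
  window $[\text{onset} - \mathrm{SPH} - \mathrm{SOP}, \text{onset} -
  \mathrm{SPH})$ a correct alarm would have occupied; without that
  credit, misses could not lower sensitivity. This interpretation is a
  documented design decision.
* **Corrected TIW**: $(\mathrm{TIW} - \text{true-alarm time}) /
  (\text{total} - \text{true-alarm time})$ — the false-warning burden
  on time not legitimately in warning. It also serves as the FPR axis
  of the threshold-swept ROC, which keeps the rate within $[0, 1]$
  (counting miss-credit windows as negatives would let false-alarm
  time exceed the negative total).
* **FDR/hr**: false-positive alarms per evaluable hour.
* **Threshold sweep**: 101 evenly spaced thresholds plus every
  observed probability; AUROC by trapezoid over the (corrected TIW,
  sensitivity) curve with ties ordered to form a staircase, AUPRC by
  step-wise (average-precision) interpolation to avoid the optimistic
  bias of trapezoidal PR areas. Curves pool subjects by concatenating
  time points (micro-averaging).

Two estimator caveats are worth stating plainly. Because a true alarm
credits its full SPH + SOP span while a missed seizure credits only an
SOP-length window, a label-independent predictor scores slightly above
0.5 whenever SPH > 0; at SPH = 0 the credits balance and chance is
0.5 (the null test runs there). And because alarms are refractory,
sensitivity is not monotone in the threshold — lowering the threshold
can trigger an alarm *earlier*, moving its warning window off the
seizure — so per-cell grid AUROCs on small cohorts are noisy.

## Calibration

Reliability tables use ten equal-width bins on $[0, 1]$ (last bin
closed), matching the usual ten-point reliability plot; ECE is the
count-weighted mean absolute gap between per-bin accuracy and
confidence. The Brier skill score is $1 - \mathrm{BS}/\mathrm{BS}_{\!ref}$
with the climatology reference $\bar p(1 - \bar p)$. For the
SPH × SOP skill grid, epochs are relabeled per horizon — positive iff
a seizure onsets within $[t + \mathrm{SPH}, t + \mathrm{SPH} +
\mathrm{SOP})$ — with per-horizon right-censoring; cells with
single-class labels report missing. Both epoch-level and
horizon-relabeled calibration are supported since either convention is
defensible; no recalibration (Platt, isotonic) is applied — the
package measures calibration, it does not repair it.

## The synthetic cohort generator

The generator exists so every downstream stage has a signal it can
provably detect; it aims at mechanism recovery, not waveform realism.
Defaults describe the study conditions: 12 subjects, half with
seizures, 1 h records at 64 Hz, eight 10–20 electrodes in homologous
pairs (F3/F4, C3/C4, O1/O2, T3/T4). Background EEG is 1/f-weighted
Gaussian noise (25 µV SD) built from a global, a pair-shared and an
individual component, giving homologous-pair correlation 0.6 versus
0.2 elsewhere so left-right structure is meaningful. Seizure subjects
carry 2–4 events with lognormal durations (median 74 s, sdlog 1.04,
truncated to 15–300 s — matching a published neonatal cohort's median
1.23 min and 0.66–2.7 min interquartile range) separated by ≥ 6 min;
events are amplitude-ramped sinusoidal discharges chirping 3 → 1.5 Hz.
Three simulated raters annotate with ±5 s boundary jitter; consensus
uses k = 2 (k = 1 degenerates correctly to a single rater).

The planted preictal signature is a linear ramp over the 300 s before
each onset that inflates variance (up to $1 + 0.15\,s$ amplitude gain)
and mixes in 8–20 Hz band-limited noise (up to $0.2\,s$ of the
background SD), both scaled by the strength parameter $s$. At $s = 0$
nothing is modified, so preictal and interictal segments are
exchangeable by construction and a forecaster must score at chance —
the null control. Everything derives bit-reproducibly from one seed
via per-subject streams.

What the generator does **not** emulate: artifacts (EMG, electrode
pops, movement), gestational-age-dependent background grading,
non-stationary sleep–wake cycling, focal seizure topography, or any
physiologically realistic preictal dynamics. Passing the end-to-end
tests therefore demonstrates that the pipeline recovers a known
planted mechanism without leakage — not that the signature, or the
achieved performance, transfers to real neonatal EEG.

A structural consequence of the 300-s signature span: alarm
configurations with SPH ≥ 300 s look entirely at pre-signature time,
so grid cells there contain no recoverable signal and their AUROCs
fluctuate around or below chance. Monotone SOP trends across the full
1–7 min grid are correspondingly diluted at this desk scale; the
trends are clear in the SPH ≤ 4 min rows where signal exists.

## Problem sizes and numerical choices

The default end-to-end runs (tests and the acceptance script) use the
12-subject, 1-h cohort: ~2 160 epochs, 120 features, ~1 300 training
windows per fold before augmentation. These sizes were chosen so the
full pipeline — including ten ConvLSTM trainings — completes in
minutes on a single CPU while leaving the planted signature
detectable. Grid sweeps use 33 thresholds per cell (the single-cell
sweep uses the dense default). EDF round trips are exact up to the
16-bit quantization step, with physical limits stored at two decimals
and the scale computed from the stored value so writer and reader
agree. Degenerate inputs (constant epochs, all-zero spectra,
single-class folds, empty calibration bins) follow flagged conventions
rather than producing NaN, and undefined metrics (sensitivity with no
seizure-associated time, BSS on single-class labels) are reported
missing rather than zero.

## Known limitations

* The reference ConvLSTM is a compact stand-in for the benchmarked
  deep architectures; only its contract, not its topology, is claimed.
* Proix-style sensitivity with miss credit is one of several
  defensible readings of the time-point denominator; the choice is
  flagged above and localized in `tally()`.
* Pure-R training is practical at desk scale but not for
  hundreds of hours of EEG; the plugin contract is the intended escape
  hatch.
* Alarm-grid AUROCs inherit the refractory-trigger noise discussed
  above; on cohorts of this size individual cells carry substantial
  variance.
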