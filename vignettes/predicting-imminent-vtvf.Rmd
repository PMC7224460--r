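---
title: "Methods: ECG-based prediction of imminent VT/VF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG-based prediction of imminent VT/VF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtvfpredict)
```

## The problem and the model

Sustained ventricular tachycardia or fibrillation (VT/VF) lasting more
than 30 seconds is malignant: it can collapse cardiac output and cause
sudden cardiac death. Minutes before onset, subtle changes appear in the
ordinary-looking beats of the ECG — heart rate creeps up, beat-to-beat
variability changes, the QRS complex deforms. This package implements a
prediction pipeline that turns those precursors into a per-minute
classification: from each one-minute ECG segment it extracts twelve
time-domain features of the R-peaks and QRS complexes, and a decision
tree classifies the segment as normal or pre-VT/VF. Performance is
reported separately for five 5-minute intervals before the annotated
onset, because the clinically interesting question is not only *whether*
but *how early* the precursors are detectable.

The pipeline assumes: a single ECG lead with identifiable QRS complexes
(records dominated by aberrant rhythms are excluded from the curated
roster); onset times supplied by annotation, not detected by the package;
and two classes only — it does not grade risk or localize the arrhythmia.

## Preprocessing

Records are truncated to 35 minutes so both source databases contribute
records of equal length, then de-outliered, then cut into one-minute
segments (7,680 samples at 128 Hz, 15,000 at 250 Hz). Segments at or
after the segment containing the onset are dropped: the classifier must
never see VT/VF itself, only its precursors. The minutes-before-onset tag
of a positive segment is measured from the segment *end*, since that is
when a deployed predictor would issue its decision.

The outlier rule is a package design choice, constrained only by the
requirement that outliers be replaced by their preceding value: a sample
is an outlier when it deviates from a 1-second sliding-window median by
more than 3 scaled MADs of that window, and is replaced by the nearest
preceding clean value. The MAD criterion adapts to local amplitude, never
fabricates values, is idempotent, and declares a locally constant signal
(MAD 0) outlier-free. Both `window_s` and `n_mad` are exposed.

## R-peak detection and fiducial points

Detection follows the Pan-Tompkins chain with its canonical parameter
values: band-pass 5–15
Hz (where QRS energy concentrates), 5-point derivative, squaring, 150 ms
moving-window integration, 200 ms refractory period, threshold update
fraction 0.125, search-back at 1.66 × the running RR average. Two choices
deserve note:

* filtering is **zero-phase** (`signal::filtfilt` with a 2nd-order
  Butterworth), so fiducial indices on the filtered signal are not
  lag-shifted against the raw signal;
* the first 2 seconds initialize the adaptive thresholds, but confident
  peaks found there are still reported.

Q and S are the signal minima in 100 ms windows before/after each R-peak
(clipped at neighbouring beats — physiological QRS bounds make 100 ms
generous). QRS onset and offset are found by scanning outward from Q and
S for the first sample whose centered slope falls below 2.5% of the
beat's maximum absolute slope, bounded at 80 ms; how flat counts as
"nearly zero" is inherently a tuning question, so `slope_eps` is an
exposed parameter. A validator discards beats with broken ordering
(Qon ≤ Q < R < S ≤ Soff) or QRS duration outside 40–200 ms; the
validator bounds are likewise package choices.

## Features and their conventions

Four RR statistics and eight QRS-morphology statistics are computed per
segment. Three definitional ambiguities that commonly afflict these
statistics were resolved as follows, each with the alternative variant
available behind a flag:

* **Heart rate.** Dividing 60 by the *total* RR time yields a quantity in
  min⁻¹ only for a single interval; we use mHR = 60/mean(RR) — the
  standard beats-per-minute definition, consistent with the mean-RR
  formula and with the invariant mRR · mHR = 60 (asserted to 1e−9 in the
  tests). The mean of instantaneous rates 60/RRᵢ is available via
  `mode = "mean_inst"`.
* **Denominators.** HRV formulas are often written with n = "total number
  of beats" although the sums have one (or two) fewer terms. We divide by
  the number of summed terms (`denominator = "terms"`); the literal
  beats-count convention is `denominator = "beats"`. SDNN and all
  morphology SDs are population-style (divide by the term count).
* **Amplitude baseline.** Q/R/S amplitudes are measured on the raw
  (de-outliered) signal — band-pass filtering distorts amplitude —
  relative to a per-beat isoelectric estimate, the signal value at Qon.
  This makes amplitudes invariant under constant offsets.

## Feature selection

Predictor importance is the sum over branch nodes splitting on a feature
of (parent risk − child risks), divided by the total number of branch
nodes; never-used features score exactly 0. The tree is a deterministic
CART implemented in-package: exhaustive split search, ties in gain broken
by lowest feature index then lowest threshold, no pruning, minimum split
size 10, minimum leaf size 1. Determinism plus stored node risks make the
conservation law Σ Imp × branch-count = total risk reduction exactly
testable, which is why the tree is not delegated to an external library
(rpart serves as an independent cross-check in the tests). Because fits
are deterministic, no RNG seed enters the tree itself; all randomness
lives in the fold partitions. One consequence of pure gain-based growth:
on a zero-gain landscape such as 4-point XOR the tree stops at the root —
greedy CART cannot see two-step interactions with no first-step gain.

Impurity is Gini by default; squared-error on the 0/1 labels (`"mse"`)
is available and orders binary splits identically up to a factor of two.

The feature-count profile fits trees on the top-k ranked features for
k = 1..12 under stratified 10-fold CV, repeated with seeds 1–5 (a fixed
five-seed repetition protocol; partitions are a seeded shuffle followed
by per-class round-robin). Feature ranking is computed
once, before fold splitting (the OUT protocol; the IN variant re-ranks
inside every training fold and is available via `cv_config`). The
pooled test-fold MSE of 0/1 predictions equals the misclassification
rate. The optimal subset is the smallest k whose mean MSE lies within one
SD (at the minimizing k) of the minimum mean MSE — a formalization of the
verbal argument that a cheaper set with equal sensitivity and slightly
lower specificity is preferable; when a per-k SE table is supplied,
equal-SE candidates resolve to the smallest k (lowest prediction
latency).

## Classification and evaluation

Positives are binned into intervals ((r−1)·5, r·5] minutes before onset,
r = 1..5; rows beyond 25 minutes are discarded. Negatives are matched by
record-minute position — normal-record segments at the same
`index_in_record` slots as the interval's positives — which balances each
interval without reusing unrelated minutes. One model is trained per
interval, matching the interval-wise framing of the analysis; a single
global model evaluated per interval is the natural alternative and is a
deliberate non-default.

Classifier defaults stay at widely used reference settings: CART as
above;
Gaussian naive Bayes with a variance floor of 1e−9 × the pooled feature
variance and posterior ties resolved to class 0 (favoring specificity);
linear-kernel soft-margin SVM with box constraint 1 and no
standardization (`e1071::svm`). Evaluation pools TP/FP/TN/FN over the
test folds of a stratified 5-fold CV per seed (seeds 1–5), then averages
SE and SP across seeds.

Report tables carry per-interval rows plus Average and SD summary rows
over the five interval values. The SD row uses the **sample** formula —
the convention under which the package's reference summary values
reproduce exactly (SE values 86.67, 88.89, 82.50, 95.00, 93.33 give
Average 89.28, SD 5.05) — which the tests assert.
Population SD sits behind `sd_mode = "population"`.

Execution time is the median wall-clock per prediction call, measured
over batches sized to exceed timer resolution after a warm-up call.
Absolute values are hardware-bound and only ordinal use is supported —
the tests assert that a tree on the 8-feature optimal set is not slower
than one on all 12 features, using interleaved measurement rounds so that
machine-load drift cancels.

## The synthetic data generator

`synth_ecg_record()` builds each beat as five Gaussian bumps (P, Q, R, S,
T) around the R time: analytic morphology gives exact per-beat ground
truth for every fiducial, which dynamical-system ECG models do not. RR
intervals are mean + truncated Gaussian jitter, optionally modulated by a
slow two-sinusoid wander (40 s and 5 min periods) emulating respiratory
and autonomic heart-rate variation; `rr_wander_amp` defaults to 0 so that
jitter-free records stay strictly periodic for timing-stability tests.
A pre-onset record carries an onset annotation and, optionally, a linear
parameter drift — RR shortening and QRS widening toward onset — as a
surrogate for pre-arrhythmic trends. No VT/VF waveform is simulated: the
pipeline never analyzes the arrhythmia itself, only the minutes before.

`synth_study_corpus()` fixes the study conditions: 9 normal records at
128 Hz and 9 pre-onset records at 250 Hz, 35 minutes each, onset at
minute 30 (populating all five intervals with 9 × 5 = 45 positives), with
subject-level parameters (resting RR 0.80 ± 0.07 s vs 0.76 ± 0.07 s, QRS
width 80 ± 7 ms vs 86 ± 7 ms, jitter, amplitudes) drawn per record so
between-subject variability is comparable to the class effect — chosen
once as physiologically plausible values.

**What passing tests do not show.** The synthetic corpus is far cleaner
than clinical ECG: no electrode artifacts, ectopic beats, baseline
wander beyond the modeled sinusoids, or morphology classes. Pipeline
SE/SP on it sit near the ceiling (~95–99%), well above what real
pre-VT/VF data yields; the corpus validates correctness and parameter
recovery (heart rate within 2 bpm, detection sensitivity ≥ 95% at 10 dB
SNR, monotone SDNN recovery), not clinical performance. The
clinical-performance check in the acceptance tests therefore requires
the real curated feature table, which cannot be redistributed here, and
reports a failure until it is supplied.

## Numerical notes and problem sizes

* Sample indices are 0-based; segment windows are half-open
  [start, start + 60·fs).
* QRS durations are quantized at the sampling period (7.8 ms at 128 Hz),
  which bounds cross-rate agreement of `mQRSd` more coarsely than the
  rate-free RR features; the tests allow for this.
* Fold partitions that leave a fold without both classes are re-drawn
  with an incremented sub-seed (logged); intervals with fewer positives
  than folds reduce the fold count.
* WFDB support covers single-signal format-16 records with a plain-text
  annotation sidecar; gain converts ADC units to mV, and the write/read
  round trip is exact to one quantization step.
* Default test and acceptance runs use the full 18-record, 35-minute
  corpus (~585 feature rows) for the end-to-end path and reduced corpora
  (2–4 records, 3–6 minutes) for orchestration smoke tests; the RR and
  confusion-statistic oracles run 1,000 randomized cases each.

## Known limitations

Only Q-R-S structures are delineated (no P/T delineation, no QT or
T-wave-alternans features); no frequency-domain HRV; no resampling
between rates (features are rate-aware instead); rhythm onset comes from
annotations only. The SVM is deliberately left at its plain defaults —
unscaled features put it at a disadvantage, visible in its specificity —
because the comparison evaluates every classifier under one fixed
protocol rather than tuning each.
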