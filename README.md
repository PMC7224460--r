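# vtvfpredict

Predicting imminent malignant ventricular arrhythmia (MVA) — sustained
ventricular tachycardia or fibrillation — from single-lead ECG, minutes
before onset. The package is aimed at biomedical-signal researchers who
want a complete, reproducible pipeline from raw ECG samples to
interval-stratified prediction performance, with every stage testable on
ground-truthed synthetic data.

## What it computes

The pipeline has four stages:

1. **Preprocessing** — records are truncated to 35 minutes, amplitude
   outliers are replaced by their preceding clean value, and the signal is
   partitioned into one-minute segments (7,680 samples at 128 Hz, 15,000 at
   250 Hz). For pre-onset records, segments at or after the annotated
   VT/VF onset are excluded; retained positive segments are tagged with
   minutes-before-onset.
2. **Fiducial detection** — a Pan-Tompkins-style detector (5–15 Hz
   zero-phase band-pass, 5-point derivative, squaring, 150 ms moving
   integration, adaptive signal/noise thresholds with search-back) finds
   R-peaks; Q and S are the local minima in 100 ms windows around each R;
   QRS onset (Qon) and offset (Soff) are found by nearly-zero-slope search;
   beats failing ordering or the 40–200 ms QRS-duration bounds are
   discarded.
3. **Feature extraction** — 12 time-domain features per segment, in
   canonical order `mRR, mHR, SDNN, RMSSD, mQRSd, sdQRSd, mQamp, sdQamp,
   mRamp, sdRamp, mSamp, sdSamp`:

   - mHR = 60 / mean(RR)   (beats/min)
   - mRR = (1/m) Σ RRᵢ   (s, m = number of intervals)
   - RMSSD = sqrt( (1/(m−1)) Σ (RRᵢ₊₁ − RRᵢ)² )
   - SDNN = sqrt( (1/m) Σ (RRᵢ − mRR)² )
   - mean and population SD of QRS duration (Soff − Qon)/fs and of the
     Q, R, S amplitudes (mV, measured against the per-beat Qon baseline).

4. **Selection and classification** — a deterministic CART decision tree
   ranks features by predictor importance,
   Imp(f) = Σ split risk reductions on f / number of branch nodes;
   an incremental 10-fold cross-validated MSE profile (seeds 1–5, feature
   ranking fixed before fold splitting) picks the optimal subset by a
   one-SD-of-minimum rule; decision tree, Gaussian naive Bayes and linear
   SVM are then evaluated with repeated stratified 5-fold CV on five
   5-minute intervals before onset, reporting sensitivity
   SE = 100·TP/(TP+FN), specificity SP = 100·TN/(TN+FP) and per-prediction
   execution time.

A ground-truthed synthetic ECG generator (Gaussian P-Q-R-S-T morphology,
controllable RR mean/jitter/wander, QRS width, amplitudes, noise, and
pre-onset drift) stands in for database downloads and backs the test
suite.

## Worked example

```r
library(vtvfpredict)

# one synthetic minute at 75 bpm, 250 Hz
g   <- synth_ecg_record(synth_spec(fs = 250, duration_s = 60,
                                   mean_rr = 0.8, rr_jitter_sd = 0.03,
                                   seed = 42))
seg <- minute_segment("demo", 0L, g$record$samples, 250, label = 0L)
round(unlist(extract_feature_vector(seg)[1:6]), 4)
#>    mRR     mHR    SDNN   RMSSD   mQRSd  sdQRSd
#> 0.8004 74.9641  0.0327  0.0454  0.1042  0.0205
```

The detector recovered the generator's 0.8 s mean RR (mHR ≈ 75 bpm), its
30 ms RR jitter (SDNN 33 ms), and a ~100 ms QRS complex for the nominal
80 ms generator width (the zero-slope search runs to the flat shoulders
of the complex).

```r
tab <- synth_dataset(100, effect = c(mQRSd = 1.5, mHR = 0.8, SDNN = 0.6),
                     seed = 1)
imp <- estimate_importance(tab)
head(data.frame(feature = imp$ranking,
                Imp = round(unname(imp$importance[imp$ranking]), 4)), 4)
#>   feature    Imp
#> 1   mQRSd 0.0069
#> 2    SDNN 0.0033
#> 3     mHR 0.0023
#> 4  sdQRSd 0.0015
```

Features carrying a real class shift rank at the top; pure-noise features
score at or near zero. `run_pipeline()` chains every stage and writes the
importance table, the MSE-by-feature-count profile, the optimal-vs-full
comparison and the per-interval SE/SP/exT report as CSVs; the
`exec/vtvfpredict` script exposes the same run from a shell.

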