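# Shared fixtures: small synthetic signals and tables built in code.

# A clean one-minute record at the given heart rate; returns record + truth.
clean_minute <- function(bpm = 60, fs = 250, jitter = 0, noise = 0.01,
                         seed = 1) {
  synth_ecg_record(synth_spec(fs = fs, duration_s = 60,
                              mean_rr = 60 / bpm, rr_jitter_sd = jitter,
                              noise_sd = noise, seed = seed))
}

# Match detected peaks against ground truth within a tolerance (ms);
# returns the fraction of true beats detected.
peak_sensitivity <- function(detected, truth_idx, fs, tol_ms = 50) {
  tol <- round(tol_ms / 1000 * fs)
  if (length(detected) == 0L) return(0)
  mean(vapply(truth_idx, function(r) any(abs(detected - r) <= tol),
              logical(1)))
}

# Confusion counts from label vectors, by direct counting (oracle).
count_confusion <- function(truth, pred) {
  list(TP = sum(pred == 1 & truth == 1), FP = sum(pred == 1 & truth == 0),
       TN = sum(pred == 0 & truth == 0), FN = sum(pred == 0 & truth == 1))
}

# Interleaved execution-time comparison: alternating measurement rounds
# cancel slow machine-load drift; the first round is a discarded warm-up.
timed_pair <- function(model_a, model_b, rows, rounds = 5, reps = 10) {
  measure_execution_time(model_a, rows, reps)
  measure_execution_time(model_b, rows, reps)
  pairs <- replicate(rounds, c(
    as.numeric(measure_execution_time(model_a, rows, reps)),
    as.numeric(measure_execution_time(model_b, rows, reps))))
  c(stats::median(pairs[1, ]), stats::median(pairs[2, ]))
}
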