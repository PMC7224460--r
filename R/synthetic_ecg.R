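#' Specification for a synthetic ECG record
#'
#' Controls a ground-truthed quasi-periodic ECG: each beat is a sum of
#' Gaussian bumps (P, Q, R, S, T) around the R-peak, RR intervals are drawn
#' as `mean_rr` plus Gaussian jitter truncated at three SDs, and white
#' noise is added. An optional onset minute marks the record as pre-VT/VF,
#' and an optional drift shortens RR and widens QRS progressively toward
#' the onset — a surrogate for the pre-arrhythmic trends the features are
#' designed to pick up, not a simulation of VT/VF waveforms.
#'
#' @param fs Sampling frequency (Hz).
#' @param duration_s Record duration (s).
#' @param mean_rr Mean RR interval (s), > 0.2.
#' @param rr_jitter_sd SD of white RR jitter (s).
#' @param rr_wander_amp Relative amplitude of a slow (40 s and 5 min
#'   period) sinusoidal modulation of the RR interval, emulating
#'   respiratory and autonomic heart-rate wander; 0 disables it.
#' @param qrs_width_ms Nominal QRS width (ms); Q and S bumps sit at
#'   +/- 0.4 of this width around R.
#' @param q_amp,r_amp,s_amp Q/R/S bump amplitudes (mV; Q and S usually
#'   negative).
#' @param p_amp,t_amp P/T bump amplitudes (mV).
#' @param noise_sd Additive white-noise SD (mV).
#' @param seed RNG seed.
#' @param onset_minute Optional minute (from record start) of the simulated
#'   VT/VF onset annotation.
#' @param drift Optional list with `rr_shorten_frac` and `qrs_widen_frac`:
#'   fractional change reached at the onset, ramped linearly from the
#'   record start.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(fs = 250, duration_s = 60, mean_rr = 0.8,
                       rr_jitter_sd = 0.02, rr_wander_amp = 0,
                       qrs_width_ms = 80,
                       q_amp = -0.1, r_amp = 1.0, s_amp = -0.2,
                       p_amp = 0.1, t_amp = 0.3, noise_sd = 0.02,
                       seed = 1L, onset_minute = NULL, drift = NULL) {
  if (mean_rr < 0.2)
    stop("mean_rr below 0.2 s is physiologically impossible: config error")
  stopifnot(fs > 0, duration_s > 0, rr_jitter_sd >= 0, qrs_width_ms > 0,
            noise_sd >= 0)
  structure(list(fs = fs, duration_s = duration_s, mean_rr = mean_rr,
                 rr_jitter_sd = rr_jitter_sd, rr_wander_amp = rr_wander_amp,
                 qrs_width_ms = qrs_width_ms,
                 q_amp = q_amp, r_amp = r_amp, s_amp = s_amp,
                 p_amp = p_amp, t_amp = t_amp, noise_sd = noise_sd,
                 seed = as.integer(seed), onset_minute = onset_minute,
                 drift = drift),
            class = "synth_spec")
}

#' Generate a synthetic ECG record with ground truth
#'
#' @param spec A [synth_spec()].
#' @return List with `record` (an [ecg_record()]) and `truth`: a data
#'   frame of per-beat 0-based ground-truth fiducials (`r_idx`, `q_idx`,
#'   `s_idx`, `qon_idx`, `soff_idx`) and the per-beat `qrs_width_s`, plus
#'   attribute-free vectors `rr_s` (drawn RR sequence).
#' @export
synth_ecg_record <- function(spec) {
  set.seed(spec$seed)
  fs <- spec$fs
  n <- as.integer(round(spec$duration_s * fs))
  onset_s <- if (is.null(spec$onset_minute)) Inf else spec$onset_minute * 60
  progress <- function(t) {            # 0 at start, 1 at onset
    if (!is.finite(onset_s)) 0 else min(1, max(0, t / onset_s))
  }
  dr_rr <- if (is.null(spec$drift)) 0 else spec$drift$rr_shorten_frac %||% 0
  dr_w <- if (is.null(spec$drift)) 0 else spec$drift$qrs_widen_frac %||% 0

  # slow heart-rate wander: two sinusoids with random phases
  ph <- stats::runif(2, 0, 2 * pi)
  wander <- function(t) {
    if (spec$rr_wander_amp == 0) return(0)
    spec$rr_wander_amp * (sin(2 * pi * t / 40 + ph[1L]) +
                          0.6 * sin(2 * pi * t / 300 + ph[2L]))
  }
  # draw beat times sequentially with (possibly drifting) mean RR
  r_times <- numeric(0)
  rr_s <- numeric(0)
  t <- 0.4                              # first beat well inside the record
  while (t < spec$duration_s - 0.4) {
    r_times <- c(r_times, t)
    jit <- spec$rr_jitter_sd *
      max(-3, min(3, stats::rnorm(1)))
    rr <- spec$mean_rr * (1 - dr_rr * progress(t)) * (1 + wander(t)) + jit
    rr <- max(0.25, rr)
    rr_s <- c(rr_s, rr)
    t <- t + rr
  }
  nb <- length(r_times)
  w_s <- (spec$qrs_width_ms / 1000) * (1 + dr_w * vapply(r_times, progress,
                                                         numeric(1)))
  x <- numeric(n)
  q_off <- 0.4 * w_s                    # Q/S bump centers relative to R (s)
  sig_qs <- w_s / 10
  sig_r <- w_s / 8
  for (b in seq_len(nb)) {
    rt <- r_times[b]
    # per-beat bump table: center (s), amplitude (mV), sigma (s)
    centers <- c(rt - 0.22, rt - q_off[b], rt, rt + q_off[b], rt + 0.30)
    amps <- c(spec$p_amp, spec$q_amp, spec$r_amp, spec$s_amp, spec$t_amp)
    sigmas <- c(0.010, sig_qs[b], sig_r[b], sig_qs[b], 0.030)
    lo <- max(1L, as.integer(floor((rt - 0.40) * fs)) + 1L)
    hi <- min(n, as.integer(ceiling((rt + 0.45) * fs)) + 1L)
    if (lo > hi) next
    tt <- ((lo:hi) - 1L) / fs
    beat <- numeric(length(tt))
    for (k in 1:5)
      beat <- beat + amps[k] * exp(-((tt - centers[k])^2) / (2 * sigmas[k]^2))
    x[lo:hi] <- x[lo:hi] + beat
  }
  if (spec$noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd)

  onset_sample <- NULL
  cls <- "normal"
  if (is.finite(onset_s)) {
    onset_sample <- as.integer(round(onset_s * fs))
    if (onset_sample >= n) onset_sample <- n - 1L
    cls <- "pre_vtvf"
  }
  rec <- ecg_record(sprintf("synth%04d", spec$seed), x, fs,
                    source_class = cls, onset_sample = onset_sample)
  ext <- q_off + 3 * sig_qs             # QRS extent beyond R on each side
  truth <- data.frame(
    r_idx = as.integer(round(r_times * fs)),
    q_idx = as.integer(round((r_times - q_off) * fs)),
    s_idx = as.integer(round((r_times + q_off) * fs)),
    qon_idx = as.integer(round((r_times - ext) * fs)),
    soff_idx = as.integer(round((r_times + ext) * fs)),
    qrs_width_s = w_s)
  list(record = rec, truth = truth, rr_s = rr_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic study corpus
#'
#' The default study conditions: nine normal records at 128 Hz and nine
#' pre-onset records at 250 Hz, each 35 minutes, pre-onset records
#' annotated at minute 30 with RR shortening and QRS widening toward the
#' onset (so all five 5-minute intervals receive positives; 9 records x 5
#' minutes = 45 per interval). Each record draws its own subject-level
#' parameters (resting RR, HRV, QRS width and amplitudes) so that
#' between-subject variability is comparable to the class effect —
#' pre-onset changes in real ECG are subtle, and a corpus without subject
#' variability would make the classification task trivially separable.
#'
#' @param seed Base RNG seed; record b uses `seed * 100 + b`.
#' @param n_normal,n_pre Record counts per class.
#' @param duration_min Record length in minutes.
#' @param onset_minute Onset minute for pre-onset records.
#' @return List of [ecg_record()]s.
#' @export
synth_study_corpus <- function(seed = 1L, n_normal = 9L, n_pre = 9L,
                               duration_min = 35, onset_minute = 30) {
  recs <- vector("list", n_normal + n_pre)
  draw_subject <- function(s, pre) {
    set.seed(s)
    # subject-level physiology; pre-onset class shifts are small relative
    # to the between-subject spread
    list(mean_rr = max(0.45, stats::rnorm(1, if (pre) 0.76 else 0.80, 0.07)),
         rr_jitter_sd = max(0.008, stats::rnorm(1,
                            if (pre) 0.040 else 0.032, 0.010)),
         rr_wander_amp = max(0.01, stats::rnorm(1, 0.04, 0.015)),
         qrs_width_ms = max(60, stats::rnorm(1, if (pre) 86 else 80, 7)),
         r_amp = max(0.5, stats::rnorm(1, 1.0, 0.15)),
         q_amp = -abs(stats::rnorm(1, if (pre) 0.12 else 0.10, 0.03)),
         s_amp = -abs(stats::rnorm(1, if (pre) 0.23 else 0.20, 0.05)))
  }
  for (b in seq_len(n_normal)) {
    subj <- draw_subject(seed * 100L + b, pre = FALSE)
    sp <- synth_spec(fs = 128, duration_s = duration_min * 60,
                     mean_rr = subj$mean_rr,
                     rr_jitter_sd = subj$rr_jitter_sd,
                     rr_wander_amp = subj$rr_wander_amp,
                     qrs_width_ms = subj$qrs_width_ms,
                     q_amp = subj$q_amp, r_amp = subj$r_amp,
                     s_amp = subj$s_amp, noise_sd = 0.02,
                     seed = seed * 100L + b)
    recs[[b]] <- synth_ecg_record(sp)$record
    recs[[b]]$record_id <- sprintf("norm%02d", b)
  }
  for (b in seq_len(n_pre)) {
    subj <- draw_subject(seed * 100L + n_normal + b, pre = TRUE)
    sp <- synth_spec(fs = 250, duration_s = duration_min * 60,
                     mean_rr = subj$mean_rr,
                     rr_jitter_sd = subj$rr_jitter_sd,
                     rr_wander_amp = subj$rr_wander_amp,
                     qrs_width_ms = subj$qrs_width_ms,
                     q_amp = subj$q_amp, r_amp = subj$r_amp,
                     s_amp = subj$s_amp, noise_sd = 0.02,
                     seed = seed * 100L + n_normal + b,
                     onset_minute = onset_minute,
                     drift = list(rr_shorten_frac = 0.10,
                                  qrs_widen_frac = 0.15))
    recs[[n_normal + b]] <- synth_ecg_record(sp)$record
    recs[[n_normal + b]]$record_id <- sprintf("pre%02d", b)
  }
  recs
}

#' Generate a two-class synthetic feature table
#'
#' Class-conditional Gaussians over the 12 canonical features: class 0 is
#' standard normal per feature; class 1 is shifted by `effect` (in SD
#' units, recycled or named per feature) with unit variance. Positives get
#' `minutes_before_onset` drawn uniformly over (0, 25] and a matching
#' `index_in_record` minute slot; negatives cover the same minute slots so
#' interval matching finds partners.
#'
#' @param n_per_class Rows per class (>= the CV fold count to be usable
#'   downstream).
#' @param effect Numeric scalar or named vector of per-feature mean shifts
#'   (SD units) for class 1.
#' @param seed RNG seed.
#' @return A feature-table data frame.
#' @export
synth_dataset <- function(n_per_class, effect = 0, seed = 1L) {
  set.seed(seed)
  feats <- feature_names()
  shift <- stats::setNames(numeric(12), feats)
  if (is.null(names(effect))) {
    shift[] <- effect
  } else {
    unknown <- setdiff(names(effect), feats)
    if (length(unknown) > 0L)
      stop("unknown feature(s) in effect: ", paste(unknown, collapse = ", "))
    shift[names(effect)] <- effect
  }
  x0 <- matrix(stats::rnorm(n_per_class * 12), ncol = 12,
               dimnames = list(NULL, feats))
  x1 <- matrix(stats::rnorm(n_per_class * 12), ncol = 12,
               dimnames = list(NULL, feats))
  x1 <- sweep(x1, 2, shift, `+`)
  mbo <- stats::runif(n_per_class, 0, 25)
  mbo[mbo == 0] <- 25
  tab <- rbind(
    data.frame(x0, label = 0L, minutes_before_onset = NA_real_,
               record_id = "synth_norm",
               index_in_record = (seq_len(n_per_class) - 1L) %% 35L),
    data.frame(x1, label = 1L, minutes_before_onset = mbo,
               record_id = "synth_pre",
               index_in_record = (seq_len(n_per_class) - 1L) %% 35L))
  rownames(tab) <- NULL
  tab
}
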