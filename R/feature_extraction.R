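#' RR intervals from detected R-peaks
#'
#' @param r_peaks An [r_peak_list()] or 0-based index vector.
#' @param fs Sampling frequency (Hz); taken from the peak list if supplied.
#' @return Numeric vector of RR intervals in seconds (length
#'   `n_peaks - 1`); empty, with a warning, for fewer than two peaks.
#' @export
rr_intervals <- function(r_peaks, fs = NULL) {
  if (inherits(r_peaks, "r_peak_list")) {
    fs <- r_peaks$fs
    idx <- r_peaks$indices
  } else idx <- as.integer(r_peaks)
  if (is.null(fs)) stop("fs required")
  if (length(idx) < 2L) {
    warning("fewer than two R-peaks; no RR intervals")
    return(numeric(0))
  }
  diff(idx) / fs
}

#' Mean heart rate
#'
#' Heart rate in beats per minute: `60 / mean(rr)`, the reciprocal of the
#' average beat period. An alternative convention — the mean of the
#' instantaneous rates `60 / rr_i` — is available via `mode`.
#'
#' @param rr RR intervals in seconds.
#' @param mode `"mean_rr"` (default) or `"mean_inst"`.
#' @return Heart rate in beats/min.
#' @export
compute_hr <- function(rr, mode = c("mean_rr", "mean_inst")) {
  mode <- match.arg(mode)
  if (length(rr) == 0L) return(NA_real_)
  if (any(rr <= 0)) stop("non-positive RR interval: data error")
  switch(mode,
         mean_rr = 60 / mean(rr),
         mean_inst = mean(60 / rr))
}

#' Mean RR interval
#'
#' Arithmetic mean of the RR intervals (the `denominator` flag switches the
#' divisor from the number of interval terms to the number of beats, i.e.
#' terms + 1, reproducing the looser textual convention in which `n` counts
#' beats).
#'
#' @param rr RR intervals (s).
#' @param denominator `"terms"` (default) or `"beats"`.
#' @return Mean RR (s); `NA` for empty input.
#' @export
compute_mrr <- function(rr, denominator = c("terms", "beats")) {
  denominator <- match.arg(denominator)
  if (length(rr) == 0L) return(NA_real_)
  sum(rr) / switch(denominator, terms = length(rr), beats = length(rr) + 1L)
}

#' Root mean square of successive RR differences
#'
#' @inheritParams compute_mrr
#' @return RMSSD (s); `NA` for fewer than two intervals.
#' @export
compute_rmssd <- function(rr, denominator = c("terms", "beats")) {
  denominator <- match.arg(denominator)
  if (length(rr) < 2L) return(NA_real_)
  d2 <- diff(rr)^2
  den <- switch(denominator, terms = length(d2), beats = length(rr) + 1L)
  sqrt(sum(d2) / den)
}

#' Standard deviation of RR intervals (SDNN)
#'
#' Population-style: the divisor is the number of summed terms, consistent
#' with the printed definition.
#'
#' @inheritParams compute_mrr
#' @return SDNN (s); 0 for a single interval, `NA` for empty input.
#' @export
compute_sdnn <- function(rr, denominator = c("terms", "beats")) {
  denominator <- match.arg(denominator)
  if (length(rr) == 0L) return(NA_real_)
  if (length(rr) == 1L) return(0)
  dev2 <- (rr - mean(rr))^2
  den <- switch(denominator, terms = length(rr), beats = length(rr) + 1L)
  sqrt(sum(dev2) / den)
}

# population SD (divide by n), the convention shared by the QRS-morphology
# feature SDs
pop_sd <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' QRS duration and amplitude features
#'
#' For each valid beat: QRS duration is `(soff - qon) / fs`; the Q, R and S
#' amplitudes are the (de-outliered, unfiltered) signal values at the
#' respective fiducials minus the per-beat isoelectric baseline, estimated
#' as the signal value at the QRS onset. Means and population SDs are taken
#' over valid beats.
#'
#' @param samples Raw (de-outliered) signal (mV).
#' @param fs Sampling frequency (Hz).
#' @param fiducials Validated fiducial set ([validate_fiducials()]).
#' @return Named list `mQRSd`, `sdQRSd`, `mQamp`, `sdQamp`, `mRamp`,
#'   `sdRamp`, `mSamp`, `sdSamp` (durations s, amplitudes mV).
#' @export
compute_qrs_amplitude_features <- function(samples, fs, fiducials) {
  f <- fiducials[fiducials$valid, , drop = FALSE]
  if (nrow(f) == 0L) stop("no valid beats; segment dropped")
  qrsd <- (f$soff_idx - f$qon_idx) / fs
  base <- samples[f$qon_idx + 1L]
  qa <- samples[f$q_idx + 1L] - base
  ra <- samples[f$r_idx + 1L] - base
  sa <- samples[f$s_idx + 1L] - base
  list(mQRSd = mean(qrsd), sdQRSd = pop_sd(qrsd),
       mQamp = mean(qa), sdQamp = pop_sd(qa),
       mRamp = mean(ra), sdRamp = pop_sd(ra),
       mSamp = mean(sa), sdSamp = pop_sd(sa))
}

#' Extract the 12-feature vector of a one-minute segment
#'
#' Full per-segment pipeline: R-peak detection on the band-passed signal,
#' Q/S localization, onset/offset search, beat validation, then the four
#' RR statistics and eight QRS-morphology statistics. Deterministic for a
#' fixed segment and configuration.
#'
#' @param segment A `minute_segment` (or [ecg_record()] of any duration
#'   >= 2 s).
#' @param cfg A [detector_config()].
#' @param q_window_ms,s_window_ms,slope_eps,max_extend_ms,qrsd_min_ms,qrsd_max_ms
#'   Fiducial parameters, see [locate_q_s()], [locate_onset_offset()],
#'   [validate_fiducials()].
#' @return A one-row data frame with the 12 canonical features plus
#'   `n_beats`, or `NULL` (with a message) when fewer than two valid beats
#'   remain.
#' @export
extract_feature_vector <- function(segment, cfg = detector_config(),
                                   q_window_ms = 100, s_window_ms = 100,
                                   slope_eps = 0.025, max_extend_ms = 80,
                                   qrsd_min_ms = 40, qrsd_max_ms = 200) {
  samples <- segment$samples
  fs <- segment$fs
  peaks <- tryCatch(detect_r_peaks(segment, cfg),
                    warning = function(w) r_peak_list(integer(0), fs))
  if (length(peaks$indices) < 3L) {
    message("segment dropped: fewer than 3 detected beats")
    return(NULL)
  }
  fset <- locate_q_s(samples, fs, peaks, q_window_ms, s_window_ms)
  fset <- locate_onset_offset(samples, fs, fset, slope_eps, max_extend_ms)
  fset <- withCallingHandlers(
    validate_fiducials(fset, fs, qrsd_min_ms, qrsd_max_ms),
    warning = function(w) invokeRestart("muffleWarning"))
  if (sum(fset$valid) < 2L) {
    message("segment dropped: fewer than 2 valid beats")
    return(NULL)
  }
  rr <- rr_intervals(peaks)
  qrs <- compute_qrs_amplitude_features(samples, fs, fset)
  data.frame(mRR = compute_mrr(rr), mHR = compute_hr(rr),
             SDNN = compute_sdnn(rr), RMSSD = compute_rmssd(rr),
             mQRSd = qrs$mQRSd, sdQRSd = qrs$sdQRSd,
             mQamp = qrs$mQamp, sdQamp = qrs$sdQamp,
             mRamp = qrs$mRamp, sdRamp = qrs$sdRamp,
             mSamp = qrs$mSamp, sdSamp = qrs$sdSamp,
             n_beats = length(peaks$indices))
}

#' Feature table for a whole record
#'
#' Truncates, de-outliers and segments a record, then extracts one feature
#' row per retained segment.
#'
#' @param rec An [ecg_record()].
#' @param cfg A [detector_config()].
#' @param max_minutes Truncation length (minutes).
#' @param ... Passed to [extract_feature_vector()].
#' @return A feature-table data frame (possibly 0 rows) with the canonical
#'   columns plus `n_beats`, `label`, `minutes_before_onset`, `record_id`,
#'   `index_in_record`.
#' @export
extract_record_features <- function(rec, cfg = detector_config(),
                                    max_minutes = 35, ...) {
  rec <- truncate_record(rec, max_minutes)
  rec <- replace_outliers(rec)
  segs <- segment_record(rec)
  rows <- lapply(segs, function(seg) {
    fv <- extract_feature_vector(seg, cfg, ...)
    if (is.null(fv)) return(NULL)
    fv$label <- seg$label
    fv$minutes_before_onset <- if (is.null(seg$minutes_before_onset))
      NA_real_ else seg$minutes_before_onset
    fv$record_id <- seg$record_id
    fv$index_in_record <- seg$index_in_record
    fv
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    empty <- stats::setNames(
      data.frame(matrix(numeric(0), ncol = 16)),
      c(feature_names(), "n_beats", "label", "minutes_before_onset",
        "record_id"))
    empty$index_in_record <- integer(0)
    return(empty)
  }
  do.call(rbind, rows)
}
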