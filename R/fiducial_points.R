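#' Locate Q and S points around each R-peak
#'
#' The Q point is the local minimum of the signal in a backward search
#' window before each R-peak, the S point the local minimum in a forward
#' window after it. Windows are clipped at the segment edges and at the
#' midpoint toward neighbouring R-peaks; a beat whose window vanishes after
#' clipping is marked invalid.
#'
#' @param samples Numeric signal (mV).
#' @param fs Sampling frequency (Hz).
#' @param r_peaks An [r_peak_list()] or 0-based integer vector.
#' @param q_window_ms,s_window_ms Search window lengths (ms).
#' @return A `fiducial_set` data frame with 0-based columns `r_idx`,
#'   `q_idx`, `s_idx`, `qon_idx`, `soff_idx` (the last two `NA` until
#'   [locate_onset_offset()]), and logical `valid`.
#' @export
locate_q_s <- function(samples, fs, r_peaks, q_window_ms = 100,
                       s_window_ms = 100) {
  r <- if (inherits(r_peaks, "r_peak_list")) r_peaks$indices else
    as.integer(r_peaks)
  if (length(r) == 0L) stop("r_peaks must be non-empty")
  stopifnot(q_window_ms > 0, s_window_ms > 0)
  n <- length(samples)
  qw <- as.integer(round(q_window_ms / 1000 * fs))
  sw <- as.integer(round(s_window_ms / 1000 * fs))
  r1 <- r + 1L    # 1-based for R indexing
  nb <- length(r)
  q_idx <- s_idx <- rep(NA_integer_, nb)
  valid <- rep(TRUE, nb)
  for (b in seq_len(nb)) {
    # backward window [r - qw, r), clipped at segment start and at the
    # midpoint to the previous R-peak
    lo <- r1[b] - qw
    if (b > 1L) lo <- max(lo, as.integer(ceiling((r1[b - 1L] + r1[b]) / 2)))
    lo <- max(lo, 1L)
    hi <- r1[b] - 1L
    if (lo > hi) { valid[b] <- FALSE; next }
    q_idx[b] <- lo + which.min(samples[lo:hi]) - 1L
    # forward window (r, r + sw], clipped symmetrically
    lo2 <- r1[b] + 1L
    hi2 <- r1[b] + sw
    if (b < nb) hi2 <- min(hi2, as.integer(floor((r1[b] + r1[b + 1L]) / 2)))
    hi2 <- min(hi2, n)
    if (lo2 > hi2) { valid[b] <- FALSE; next }
    s_idx[b] <- lo2 + which.min(samples[lo2:hi2]) - 1L
  }
  data.frame(r_idx = r, q_idx = q_idx - 1L, s_idx = s_idx - 1L,
             qon_idx = NA_integer_, soff_idx = NA_integer_, valid = valid)
}

#' Locate QRS onset and offset by zero-slope search
#'
#' Scanning backward from the Q point, the onset is the first sample whose
#' centered slope magnitude falls below `slope_eps` times the beat's
#' maximum absolute slope; the offset is found symmetrically forward from
#' the S point. If no near-flat sample appears within `max_extend_ms` the
#' bound index is used and the beat is flagged (kept, with `flat_found`
#' FALSE).
#'
#' @param samples,fs Signal and sampling frequency.
#' @param fset Output of [locate_q_s()].
#' @param slope_eps Fraction of the beat's maximum absolute slope counted
#'   as "nearly zero".
#' @param max_extend_ms Maximum search distance beyond Q / S (ms).
#' @return `fset` with `qon_idx`, `soff_idx` filled and a `flat_found`
#'   logical column added.
#' @export
locate_onset_offset <- function(samples, fs, fset, slope_eps = 0.025,
                                max_extend_ms = 80) {
  n <- length(samples)
  slope <- centered_slope(samples, fs)
  ext <- max(1L, as.integer(round(max_extend_ms / 1000 * fs)))
  fset$flat_found <- NA
  for (b in seq_len(nrow(fset))) {
    if (!fset$valid[b] || is.na(fset$q_idx[b]) || is.na(fset$s_idx[b])) next
    q1 <- fset$q_idx[b] + 1L
    s1 <- fset$s_idx[b] + 1L
    beat_lo <- max(1L, q1 - ext)
    beat_hi <- min(n, s1 + ext)
    smax <- max(abs(slope[beat_lo:beat_hi]))
    thr <- if (smax > 0) slope_eps * smax else Inf
    # onset: backward from Q
    qon <- beat_lo
    found_on <- FALSE
    for (i in q1:beat_lo) {
      if (abs(slope[i]) <= thr || !is.finite(thr)) { qon <- i; found_on <- TRUE; break }
    }
    # offset: forward from S
    soff <- beat_hi
    found_off <- FALSE
    for (i in s1:beat_hi) {
      if (abs(slope[i]) <= thr || !is.finite(thr)) { soff <- i; found_off <- TRUE; break }
    }
    fset$qon_idx[b] <- qon - 1L
    fset$soff_idx[b] <- soff - 1L
    fset$flat_found[b] <- found_on && found_off
  }
  fset
}

# centered first difference scaled by fs (slope in mV/s); one-sided at edges
centered_slope <- function(x, fs) {
  n <- length(x)
  s <- numeric(n)
  if (n >= 3L) s[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  if (n >= 2L) {
    s[1L] <- (x[2L] - x[1L]) * fs
    s[n] <- (x[n] - x[n - 1L]) * fs
  }
  s
}

#' Validate fiducial beats
#'
#' A beat is valid only if its fiducials are complete and ordered
#' (qon <= q < r < s <= soff) and its QRS duration lies inside
#' physiological bounds. Invalid beats are excluded from all downstream
#' feature computations.
#'
#' @param fset Fiducial set with onset/offset located.
#' @param fs Sampling frequency (Hz).
#' @param qrsd_min_ms,qrsd_max_ms QRS-duration bounds (ms).
#' @return `fset` with updated `valid` column; warns when every beat is
#'   invalid (the segment is then dropped downstream).
#' @export
validate_fiducials <- function(fset, fs, qrsd_min_ms = 40, qrsd_max_ms = 200) {
  ok <- fset$valid &
    !is.na(fset$q_idx) & !is.na(fset$s_idx) &
    !is.na(fset$qon_idx) & !is.na(fset$soff_idx)
  ord <- rep(FALSE, nrow(fset))
  ord[ok] <- fset$qon_idx[ok] <= fset$q_idx[ok] &
    fset$q_idx[ok] < fset$r_idx[ok] &
    fset$r_idx[ok] < fset$s_idx[ok] &
    fset$s_idx[ok] <= fset$soff_idx[ok]
  qrsd_ms <- (fset$soff_idx - fset$qon_idx) / fs * 1000
  in_range <- !is.na(qrsd_ms) & qrsd_ms >= qrsd_min_ms & qrsd_ms <= qrsd_max_ms
  fset$valid <- ok & ord & in_range
  if (!any(fset$valid))
    warning("all beats invalid; segment will be dropped")
  fset
}

#' Write a per-segment fiducial dump for inspection
#'
#' @param fset Fiducial set.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_fiducials <- function(fset, path) {
  out <- cbind(beat = seq_len(nrow(fset)) - 1L, fset)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
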