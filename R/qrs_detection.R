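#' Detector configuration
#'
#' Parameters of the Pan-Tompkins-style R-peak detector. Defaults are the
#' canonical values: 5-15 Hz passband (where QRS energy concentrates),
#' 150 ms integration window, 200 ms refractory period, threshold update
#' fraction 1/8, and search-back at 1.66 times the running RR average.
#'
#' @param band_low,band_high Passband edges (Hz).
#' @param integ_window_ms Moving-integration window (ms).
#' @param refractory_ms Minimum separation between reported peaks (ms).
#' @param threshold_update Fraction in (0,1) used to update the running
#'   signal/noise peak estimates.
#' @param searchback_factor Multiple of the running RR average after which a
#'   missed beat is searched for with a halved threshold.
#' @return A `detector_config` list.
#' @export
detector_config <- function(band_low = 5, band_high = 15,
                            integ_window_ms = 150, refractory_ms = 200,
                            threshold_update = 0.125,
                            searchback_factor = 1.66) {
  stopifnot(band_low > 0, band_high > band_low, integ_window_ms > 0,
            refractory_ms > 0, threshold_update > 0, threshold_update < 1,
            searchback_factor > 0)
  structure(list(band_low = band_low, band_high = band_high,
                 integ_window_ms = integ_window_ms,
                 refractory_ms = refractory_ms,
                 threshold_update = threshold_update,
                 searchback_factor = searchback_factor),
            class = "detector_config")
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the output is band-limited with zero phase lag
#' and downstream fiducial indices are not shifted.
#'
#' @param samples Numeric signal.
#' @param fs Sampling frequency (Hz).
#' @param cfg A [detector_config()].
#' @return Filtered signal, same length.
#' @export
bandpass_filter <- function(samples, fs, cfg = detector_config()) {
  if (cfg$band_high >= fs / 2)
    stop("band_high must be below the Nyquist frequency: config error")
  bf <- signal::butter(2, c(cfg$band_low, cfg$band_high) / (fs / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, samples))
}

#' Derivative, squaring and moving-window integration
#'
#' The detection envelope: a centered 5-point derivative emphasizes QRS
#' slopes, squaring rectifies and accentuates them, and a moving-window
#' mean over `integ_window_ms` merges the slopes of one complex into a
#' single hump. Edge windows are averaged over the available samples so the
#' envelope has the same length as the input.
#'
#' @inheritParams bandpass_filter
#' @param filtered Band-passed signal.
#' @return Non-negative envelope, same length as `filtered`.
#' @export
derivative_squaring_integration <- function(filtered, fs,
                                            cfg = detector_config()) {
  n <- length(filtered)
  d <- five_point_derivative(filtered, fs)
  sq <- d * d
  w <- max(1L, as.integer(round(cfg$integ_window_ms / 1000 * fs)))
  moving_mean(sq, w)
}

# centered 5-point derivative (1/8)(-x[n-2] - 2x[n-1] + 2x[n+1] + x[n+2]) * fs,
# zero-padded at the edges
five_point_derivative <- function(x, fs) {
  n <- length(x)
  xp <- c(0, 0, x, 0, 0)
  i <- seq_len(n) + 2L
  (fs / 8) * (-xp[i - 2L] - 2 * xp[i - 1L] + 2 * xp[i + 1L] + xp[i + 2L])
}

# centered moving mean with shrinking edge windows (keeps total mass for
# interior impulses and output length equal to input length)
moving_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 1L) return(x)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect R-peaks with adaptive thresholding
#'
#' Pan-Tompkins-style detection: candidate peaks are local maxima of the
#' integrated envelope; running signal and noise levels drive an adaptive
#' threshold (updated with fraction `threshold_update`); candidates within
#' the refractory period collapse to the larger; when the gap since the
#' last accepted beat exceeds `searchback_factor` times the running RR
#' average, the interval is re-searched at half threshold; each accepted
#' peak is finally refined to the local maximum of the band-passed signal
#' within one integration window. The first two seconds serve as the
#' threshold learning phase, but confident peaks found there are reported.
#'
#' @param x An [ecg_record()], `minute_segment`, or numeric vector.
#' @param cfg A [detector_config()].
#' @param fs Sampling frequency; only needed when `x` is a bare vector.
#' @return An `r_peak_list`: list with 0-based `indices` and `fs`.
#' @export
detect_r_peaks <- function(x, cfg = detector_config(), fs = NULL) {
  if (inherits(x, "ecg_record") || inherits(x, "minute_segment")) {
    fs <- x$fs
    samples <- x$samples
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric signal")
    samples <- as.numeric(x)
  }
  if (length(samples) < 2 * fs)
    stop("signal must be at least 2 s long for threshold initialization")

  filt <- bandpass_filter(samples, fs, cfg)
  env <- derivative_squaring_integration(filt, fs, cfg)
  refr <- as.integer(round(cfg$refractory_ms / 1000 * fs))
  wint <- max(1L, as.integer(round(cfg$integ_window_ms / 1000 * fs)))

  n <- length(env)
  # candidate local maxima of the envelope
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  if (length(cand) == 0L || max(env) <= 0) {
    warning("no R-peaks found")
    return(r_peak_list(integer(0), fs))
  }

  # learning phase: first 2 s set the initial signal / noise levels
  learn <- env[seq_len(min(n, as.integer(2 * fs)))]
  spk <- max(learn)            # running signal-peak estimate
  npk <- mean(learn) / 2       # running noise-peak estimate
  a <- cfg$threshold_update

  accepted <- integer(0)
  rr_avg <- NA_real_
  last <- -Inf
  thr_at <- function() npk + 0.25 * (spk - npk)

  accept <- function(i) {
    if (length(accepted) > 0L && i - last < refr) {
      # collapse to the larger envelope peak within the refractory period
      if (env[i] > env[last]) accepted[length(accepted)] <<- i
      else return(invisible())
    } else {
      accepted[length(accepted) + 1L] <<- i
    }
    last <<- accepted[length(accepted)]
    k <- length(accepted)
    if (k >= 2L) {
      rr <- diff(utils::tail(accepted, 8L))
      rr_avg <<- mean(rr)
    }
    invisible()
  }

  for (i in cand) {
    thr <- thr_at()
    if (env[i] >= thr) {
      # search-back first: did we skip a beat before this one?
      if (!is.na(rr_avg) && length(accepted) > 0L &&
          (i - last) > cfg$searchback_factor * rr_avg) {
        gap_cand <- cand[cand > last + refr & cand < i - refr]
        gap_cand <- gap_cand[env[gap_cand] >= thr / 2]
        if (length(gap_cand) > 0L) {
          ib <- gap_cand[which.max(env[gap_cand])]
          accept(ib)
          spk <- a * env[ib] + (1 - a) * spk
        }
      }
      before <- length(accepted)
      accept(i)
      if (length(accepted) > before || last == i)
        spk <- a * env[i] + (1 - a) * spk
    } else {
      npk <- a * env[i] + (1 - a) * npk
    }
  }

  if (length(accepted) == 0L) {
    warning("no R-peaks found")
    return(r_peak_list(integer(0), fs))
  }

  # refine each peak to the band-passed local maximum within +/- one window
  refined <- vapply(accepted, function(i) {
    lo <- max(1L, i - wint)
    hi <- min(n, i + wint)
    lo + which.max(filt[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory invariant after refinement
  keep <- rep(TRUE, length(refined))
  j <- 1L
  for (k in seq_along(refined)[-1L]) {
    if (refined[k] - refined[j] < refr) {
      if (filt[refined[k]] > filt[refined[j]]) keep[j] <- FALSE else keep[k] <- FALSE
      if (keep[k]) j <- k
    } else j <- k
  }
  r_peak_list(refined[keep] - 1L, fs)   # 0-based
}

#' R-peak list constructor
#'
#' @param indices Strictly increasing 0-based sample indices.
#' @param fs Sampling frequency (Hz).
#' @return An `r_peak_list`.
#' @export
r_peak_list <- function(indices, fs) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop("R-peak indices must be strictly increasing")
  structure(list(indices = indices, fs = as.numeric(fs)),
            class = "r_peak_list")
}
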