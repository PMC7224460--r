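#' Canonical feature names
#'
#' The twelve per-segment features, in the fixed canonical order used by
#' every feature table, importance ranking and report in this package:
#' mean RR interval (s), mean heart rate (bpm), SDNN (s), RMSSD (s),
#' mean and SD of QRS duration (s), and mean and SD of the Q, R and S
#' amplitudes (mV).
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("mRR", "mHR", "SDNN", "RMSSD", "mQRSd", "sdQRSd",
    "mQamp", "sdQamp", "mRamp", "sdRamp", "mSamp", "sdSamp")
}

#' Construct an ECG record
#'
#' The unit of ingestion: a single-lead ECG signal in millivolts at a fixed
#' sampling rate, optionally annotated with the sample index of the first
#' sustained VT/VF onset. Sample indexing is 0-based throughout, matching
#' WFDB conventions.
#'
#' @param record_id Character identifier.
#' @param samples Numeric vector of amplitudes (mV).
#' @param fs Sampling frequency in Hz.
#' @param source_class `"normal"` or `"pre_vtvf"`.
#' @param onset_sample Optional 0-based sample index of the first annotated
#'   sustained VT/VF onset. Must be absent for normal records.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, samples, fs,
                       source_class = c("normal", "pre_vtvf"),
                       onset_sample = NULL) {
  source_class <- match.arg(source_class)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("ECG record must contain samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (source_class == "normal" && !is.null(onset_sample))
    stop("normal records carry no onset annotation")
  if (!is.null(onset_sample)) {
    onset_sample <- as.integer(onset_sample)
    if (onset_sample < 0L || onset_sample >= length(samples))
      stop("onset_sample outside signal: annotation error")
  }
  structure(
    list(record_id = as.character(record_id), samples = samples,
         fs = as.numeric(fs), source_class = source_class,
         onset_sample = onset_sample),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.2f min), class %s%s\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs / 60, x$source_class,
              if (!is.null(x$onset_sample))
                sprintf(", onset at sample %d", x$onset_sample) else ""))
  invisible(x)
}

#' Load an ECG record from disk
#'
#' Two dialects are supported. `"csv"` expects comment-style header lines
#' (`# record_id: <id>`, `# fs: <Hz>`, optionally `# onset_sample: <n>` and
#' `# source_class: <class>`) followed by a single `sample_mv` column, one
#' sample per row, already in mV. `"wfdb"` expects a minimal single-signal
#' WFDB pair (`<rec>.hea` text header, `<rec>.dat` format-16 samples); the
#' header gain converts ADC units to mV, and a plain-text annotation sidecar
#' `<rec>.ann` (lines of `<sample> <code>`), when present, supplies the
#' first `[` (VT/VF onset) annotation.
#'
#' @param path File path (for WFDB, the `.hea` file or the headerless record
#'   stem).
#' @param format `"csv"` or `"wfdb"`.
#' @return An [ecg_record()].
#' @export
load_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  switch(format, csv = load_record_csv(path), wfdb = load_record_wfdb(path))
}

load_record_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read ECG CSV: ", path)
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(m) == 0L) return(NULL)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1L]))
  }
  fs <- get_field("fs")
  if (is.null(fs))
    stop("CSV record header missing fs: format error")
  rid <- get_field("record_id")
  if (is.null(rid)) rid <- tools::file_path_sans_ext(basename(path))
  onset <- get_field("onset_sample")
  cls <- get_field("source_class")
  if (is.null(cls)) cls <- if (is.null(onset)) "normal" else "pre_vtvf"
  dat <- utils::read.csv(path, comment.char = "#")
  if (!"sample_mv" %in% names(dat))
    stop("CSV record must contain a sample_mv column: format error")
  ecg_record(rid, dat$sample_mv, as.numeric(fs), source_class = cls,
             onset_sample = if (is.null(onset)) NULL else as.integer(onset))
}

# Minimal WFDB: single signal, format 16, little-endian int16.
parse_hea <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  sig <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]
  gain_field <- sig[3L]                         # "gain(baseline)/units" forms
  gain <- as.numeric(sub("[(/].*$", "", gain_field))
  baseline <- 0
  if (grepl("\\(", gain_field))
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
  if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default adu/mV
  list(record_id = top[1L], n_sig = as.integer(top[2L]),
       fs = as.numeric(top[3L]), n_samples = as.integer(top[4L]),
       dat_file = sig[1L], fmt = sig[2L], gain = gain, baseline = baseline)
}

load_record_wfdb <- function(path) {
  stem <- sub("\\.hea$", "", path)
  hea <- paste0(stem, ".hea")
  if (!file.exists(hea)) stop("cannot read WFDB header: ", hea)
  h <- parse_hea(hea)
  if (!is.finite(h$fs) || h$fs <= 0) stop("WFDB header missing fs: format error")
  dat <- file.path(dirname(hea), h$dat_file)
  if (!file.exists(dat)) stop("cannot read WFDB signal file: ", dat)
  if (h$fmt != "16") stop("only WFDB format 16 is supported, got format ", h$fmt)
  adu <- readBin(dat, what = "integer", n = h$n_samples, size = 2L,
                 signed = TRUE, endian = "little")
  mv <- (adu - h$baseline) / h$gain
  onset <- NULL
  ann_path <- paste0(stem, ".ann")
  if (file.exists(ann_path)) {
    ann <- utils::read.table(ann_path, header = FALSE,
                             col.names = c("sample", "code"),
                             colClasses = c("integer", "character"))
    vt <- ann$sample[ann$code == "["]
    if (length(vt) > 0L) {
      onset <- min(vt)
      if (onset >= length(mv))
        stop("annotation index beyond signal: annotation error")
    }
  }
  ecg_record(h$record_id, mv, h$fs,
             source_class = if (is.null(onset)) "normal" else "pre_vtvf",
             onset_sample = onset)
}

#' Write an ECG record in the minimal WFDB or CSV dialect
#'
#' WFDB output quantizes samples to 16-bit ADC units with the given gain;
#' the round trip through [load_record()] therefore reproduces each sample
#' within half a quantization step (1/(2*gain) mV). An onset annotation, if
#' present, is written to a `.ann` text sidecar as a `[` code.
#'
#' @param rec An [ecg_record()].
#' @param stem Output path without extension (WFDB) or full path (CSV).
#' @param format `"wfdb"` or `"csv"`.
#' @param gain ADC units per mV for WFDB quantization.
#' @return Invisibly, the header or file path written.
#' @export
write_record <- function(rec, stem, format = c("wfdb", "csv"), gain = 1000) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(stem, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# record_id: %s", rec$record_id),
                 sprintf("# fs: %g", rec$fs),
                 sprintf("# source_class: %s", rec$source_class)), con)
    if (!is.null(rec$onset_sample))
      writeLines(sprintf("# onset_sample: %d", rec$onset_sample), con)
    writeLines("sample_mv", con)
    writeLines(format(rec$samples, digits = 10, trim = TRUE, scientific = FALSE), con)
    return(invisible(stem))
  }
  hea <- paste0(stem, ".hea")
  dat_name <- paste0(basename(stem), ".dat")
  adu <- as.integer(pmax(pmin(round(rec$samples * gain), 32767), -32768))
  writeBin(adu, paste0(stem, ".dat"), size = 2L, endian = "little")
  writeLines(c(sprintf("%s 1 %g %d", rec$record_id, rec$fs, length(adu)),
               sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 ECG",
                       dat_name, gain, adu[1L])), hea)
  if (!is.null(rec$onset_sample))
    writeLines(sprintf("%d [", rec$onset_sample), paste0(stem, ".ann"))
  invisible(hea)
}

#' Truncate a record to a maximum duration
#'
#' Records are cut to at most `max_minutes` (default 35, the full length of
#' the shortest database used) so every record contributes the same number
#' of one-minute segments. An onset annotation falling beyond the cut is
#' dropped and the record reverts to class normal.
#'
#' @param rec An [ecg_record()].
#' @param max_minutes Maximum duration in minutes.
#' @return A (possibly shortened) [ecg_record()].
#' @export
truncate_record <- function(rec, max_minutes = 35) {
  stopifnot(max_minutes > 0)
  n_max <- round(max_minutes * 60 * rec$fs)
  if (length(rec$samples) <= n_max) return(rec)
  samples <- rec$samples[seq_len(n_max)]
  onset <- rec$onset_sample
  cls <- rec$source_class
  if (!is.null(onset) && onset >= n_max) {
    onset <- NULL
    cls <- "normal"
  }
  ecg_record(rec$record_id, samples, rec$fs, source_class = cls,
             onset_sample = onset)
}

#' Replace amplitude outliers by the preceding clean value
#'
#' A sample is an outlier when it deviates from its sliding-window median by
#' more than `n_mad` times the scaled median absolute deviation of the same
#' window. Outliers are overwritten with the nearest preceding non-outlier
#' value, which preserves signal length and never fabricates amplitudes. A
#' locally constant signal has MAD 0 and is declared outlier-free there.
#'
#' @param rec An [ecg_record()].
#' @param window_s Sliding window length in seconds (default 1).
#' @param n_mad Outlier threshold in scaled-MAD units (default 3).
#' @return An [ecg_record()] of identical length.
#' @export
replace_outliers <- function(rec, window_s = 1, n_mad = 3) {
  x <- rec$samples
  w <- max(3L, as.integer(round(window_s * rec$fs)))
  if (w %% 2L == 0L) w <- w + 1L
  stopifnot(w >= 3L)
  med <- stats::runmed(x, w, endrule = "median")
  absdev <- abs(x - med)
  # scaled MAD of each window: median of |x - window median|, consistency
  # factor 1.4826 for the normal distribution
  mad_w <- 1.4826 * stats::runmed(absdev, w, endrule = "median")
  is_out <- absdev > n_mad * mad_w & mad_w > 0
  is_out[1L] <- FALSE
  if (!any(is_out)) return(rec)
  y <- x
  y[is_out] <- NA_real_
  # carry the nearest preceding clean value forward
  idx <- seq_along(y)
  idx[is.na(y)] <- NA_integer_
  last_clean <- cummax_na(idx)
  y[is.na(y)] <- x[last_clean[is.na(y)]]
  ecg_record(rec$record_id, y, rec$fs, source_class = rec$source_class,
             onset_sample = rec$onset_sample)
}

# running maximum that treats NA as "keep previous" (locf on indices)
cummax_na <- function(idx) {
  notna <- !is.na(idx)
  filled <- idx
  filled[!notna] <- 0L
  out <- cummax(filled)
  out[out == 0L] <- 1L
  out
}

#' Partition a record into one-minute segments
#'
#' Consecutive non-overlapping 60-second windows. For a pre-onset record,
#' every segment whose window reaches the annotated onset — and everything
#' after it — is excluded, so no retained segment overlaps VT/VF itself.
#' Retained positive segments carry `minutes_before_onset`, measured from
#' the segment end (the moment a prediction would be issued).
#'
#' @param rec An [ecg_record()], already truncated to at most 35 minutes.
#' @return A list of `minute_segment` objects (possibly empty, with a
#'   warning, for records shorter than one minute).
#' @export
segment_record <- function(rec) {
  n_seg_len <- round(60 * rec$fs)
  n_full <- length(rec$samples) %/% n_seg_len
  if (n_full == 0L) {
    warning("record ", rec$record_id, " shorter than one minute; no segments")
    return(list())
  }
  out <- vector("list", n_full)
  keep <- logical(n_full)
  for (i in seq_len(n_full)) {
    start <- (i - 1L) * n_seg_len          # 0-based start
    end <- start + n_seg_len               # half-open [start, end)
    seg_samples <- rec$samples[(start + 1L):end]
    if (is.null(rec$onset_sample)) {
      out[[i]] <- minute_segment(rec$record_id, i - 1L, seg_samples, rec$fs,
                                 label = 0L)
      keep[i] <- TRUE
    } else {
      if (rec$onset_sample < end) {
        keep[i] <- FALSE                   # window contains (or follows) onset
      } else {
        mbo <- (rec$onset_sample - end) / (60 * rec$fs)
        out[[i]] <- minute_segment(rec$record_id, i - 1L, seg_samples, rec$fs,
                                   label = 1L, minutes_before_onset = mbo)
        keep[i] <- TRUE
      }
    }
  }
  out[keep]
}

#' Construct a one-minute segment
#'
#' @param record_id Parent record identifier.
#' @param index_in_record 0-based segment index within the record.
#' @param samples Amplitudes (mV), exactly `round(60 * fs)` of them.
#' @param fs Sampling frequency (Hz).
#' @param label 0 (normal) or 1 (pre-VT/VF).
#' @param minutes_before_onset Minutes from segment end to the annotated
#'   onset; required iff `label == 1`.
#' @return A `minute_segment` object.
#' @export
minute_segment <- function(record_id, index_in_record, samples, fs,
                           label = 0L, minutes_before_onset = NULL) {
  if (length(samples) != round(60 * fs))
    stop("minute segment must contain exactly round(60*fs) samples")
  label <- as.integer(label)
  if (label == 1L && is.null(minutes_before_onset))
    stop("positive segments must carry minutes_before_onset")
  if (label == 0L && !is.null(minutes_before_onset))
    stop("normal segments carry no onset tag")
  structure(
    list(record_id = as.character(record_id),
         index_in_record = as.integer(index_in_record),
         samples = as.numeric(samples), fs = as.numeric(fs),
         minutes_before_onset = minutes_before_onset, label = label),
    class = "minute_segment"
  )
}

#' Read a feature table
#'
#' A feature table is a data frame with the 12 canonical feature columns
#' (see [feature_names()]), a 0/1 `label` column, and optional
#' `minutes_before_onset`, `record_id`, `index_in_record` and `n_beats`
#' columns. A column map translates non-canonical headers (for externally
#' supplied tables whose exact layout differs).
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical names
#'   (names) to file column headers (values).
#' @return A `data.frame` feature table.
#' @export
read_feature_table <- function(path, column_map = NULL) {
  dat <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      from <- column_map[[canon]]
      if (from %in% names(dat)) names(dat)[names(dat) == from] <- canon
    }
  }
  required <- c(feature_names(), "label")
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0L)
    stop("feature table schema error; unmatched columns: ",
         paste(missing, collapse = ", "))
  if (!all(dat$label %in% c(0L, 1L)))
    stop("feature table labels must be 0 or 1")
  dat
}

#' Write a feature table
#'
#' @param table A feature table data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  required <- c(feature_names(), "label")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L)
    stop("feature table schema error; unmatched columns: ",
         paste(missing, collapse = ", "))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Roster of study records
#'
#' The 18 half-hour ECG records the study design calls for: nine
#' pre-VT/VF records from the malignant-ventricular-ectopy database (250
#' Hz) whose beats remain identifiable before onset, and nine normal-sinus
#' records (128 Hz). Shipped as a plain-text table under `extdata`.
#'
#' @return A data frame with columns `database`, `record`, `fs`,
#'   `source_class`.
#' @export
study_record_roster <- function() {
  path <- system.file("extdata", "study_records.csv", package = "vtvfpredict",
                      mustWork = TRUE)
  utils::read.csv(path, colClasses = c("character", "character",
                                       "numeric", "character"))
}
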