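#' Sensitivity from confusion counts
#'
#' `100 * TP / (TP + FN)`: the percentage of truly at-risk segments that
#' test positive.
#'
#' @param counts Named list/vector or data frame row with `TP`, `FN` (and
#'   optionally `FP`, `TN`).
#' @return Sensitivity in percent; `NA` when no positives exist.
#' @export
sensitivity <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  fn <- as.numeric(counts[["FN"]])
  if (tp + fn == 0) return(NA_real_)
  100 * tp / (tp + fn)
}

#' Specificity from confusion counts
#'
#' `100 * TN / (TN + FP)`: the percentage of healthy segments that test
#' negative.
#'
#' @param counts Named list/vector or data frame row with `TN`, `FP`.
#' @return Specificity in percent; `NA` when no negatives exist.
#' @export
specificity <- function(counts) {
  tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]])
  if (tn + fp == 0) return(NA_real_)
  100 * tn / (tn + fp)
}

#' Measure per-prediction execution time
#'
#' Median wall-clock time of a single prediction call over repeated
#' measurements, after one warm-up call. Absolute values are
#' hardware-dependent and are reported for ordinal comparison only (e.g. a
#' tree on fewer features is not slower than one on more).
#'
#' @param model A fitted classifier (anything `predict()` accepts).
#' @param rows Rows to predict.
#' @param repetitions Number of timed batches (>= 5).
#' @return Median execution time per prediction call in milliseconds
#'   (hardware-dependent), with the individual per-batch timings (ms)
#'   attached as attribute `"times"`.
#' @export
measure_execution_time <- function(model, rows, repetitions = 25) {
  stopifnot(repetitions >= 5)
  predict(model, rows)                       # warm-up
  # batch enough calls that one batch is well above timer resolution
  inner <- 1L
  repeat {
    t0 <- proc.time()[["elapsed"]]
    for (i in seq_len(inner)) predict(model, rows)
    dt <- proc.time()[["elapsed"]] - t0
    if (dt >= 0.02 || inner >= 65536L) break
    inner <- inner * 4L
  }
  times <- vapply(seq_len(repetitions), function(i) {
    t0 <- proc.time()[["elapsed"]]
    for (j in seq_len(inner)) predict(model, rows)
    (proc.time()[["elapsed"]] - t0) / inner
  }, numeric(1))
  structure(stats::median(times) * 1000, times = times * 1000)
}

#' Aggregate per-interval results into a report table
#'
#' Builds the per-interval SE/SP/exT table for one classifier: one row per
#' interval (seed-averaged SE and SP from the pooled confusions) plus
#' `Average` and `SD` rows taken over the interval values. The SD row uses
#' the sample formula by default — the convention that reproduces the
#' printed summary rows of the study tables — with the population formula
#' behind `sd_mode`.
#'
#' @param interval_results List of per-interval lists with elements
#'   `interval`, `confusions` (per-seed data frame from [run_cv()]) and
#'   optionally `exT` (ms).
#' @param classifier Label for the classifier column.
#' @param sd_mode `"sample"` (default) or `"population"`.
#' @return Data frame with columns `interval`, `classifier`, `SE`, `SP`,
#'   `exT`; interval is `"Average"`/`"SD"` in the summary rows.
#' @export
aggregate_report <- function(interval_results, classifier = "dt",
                             sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  sd_fun <- if (sd_mode == "sample") stats::sd else
    function(x) sqrt(mean((x - mean(x))^2))
  rows <- lapply(interval_results, function(res) {
    se <- mean(vapply(seq_len(nrow(res$confusions)), function(i)
      sensitivity(res$confusions[i, ]), numeric(1)))
    sp <- mean(vapply(seq_len(nrow(res$confusions)), function(i)
      specificity(res$confusions[i, ]), numeric(1)))
    data.frame(interval = as.character(res$interval), classifier = classifier,
               SE = se, SP = sp,
               exT = if (is.null(res$exT)) NA_real_ else as.numeric(res$exT))
  })
  tab <- do.call(rbind, rows)
  summarise <- function(fun) {
    data.frame(interval = NA_character_, classifier = classifier,
               SE = fun(tab$SE), SP = fun(tab$SP),
               exT = if (all(is.na(tab$exT))) NA_real_ else
                 fun(tab$exT[!is.na(tab$exT)]))
  }
  avg <- summarise(mean)
  avg$interval <- "Average"
  if (nrow(tab) >= 2L) {
    sdr <- summarise(sd_fun)
    sdr$interval <- "SD"
  } else {
    sdr <- avg
    sdr$interval <- "SD"
    sdr$SE <- sdr$SP <- sdr$exT <- NA_real_   # SD undefined for one interval
  }
  rbind(tab, avg, sdr)
}
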