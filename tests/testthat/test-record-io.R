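test_that("CSV records round-trip with identity and fail without fs", {
  rec <- ecg_record("r1", sin(seq_len(7680) / 10), fs = 128)
  path <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, path, format = "csv")
  back <- load_record(path, format = "csv")
  expect_equal(length(back$samples), 7680)
  expect_equal(back$fs, 128)
  expect_equal(back$samples, rec$samples, tolerance = 1e-8)
  expect_equal(back$record_id, "r1")

  # header without fs is a format error
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# record_id: x", "sample_mv", "0.1", "0.2"), bad)
  expect_error(load_record(bad, format = "csv"), "fs")
})

test_that("WFDB-dialect round trip reproduces samples within quantization", {
  g <- clean_minute(bpm = 72, fs = 128, seed = 11)
  stem <- file.path(withr::local_tempdir(), "synthrec")
  gain <- 1000
  write_record(g$record, stem, format = "wfdb", gain = gain)
  back <- load_record(paste0(stem, ".hea"), format = "wfdb")
  expect_equal(back$fs, 128)
  expect_equal(length(back$samples), length(g$record$samples))
  expect_lt(max(abs(back$samples - g$record$samples)), 1 / gain)
})

test_that("WFDB annotation sidecar populates the onset and is bounds-checked", {
  spec <- synth_spec(fs = 128, duration_s = 120, seed = 4, onset_minute = 1)
  g <- synth_ecg_record(spec)
  stem <- file.path(withr::local_tempdir(), "prerec")
  write_record(g$record, stem, format = "wfdb")
  back <- load_record(paste0(stem, ".hea"), format = "wfdb")
  expect_equal(back$source_class, "pre_vtvf")
  expect_equal(back$onset_sample, 60 * 128L)

  writeLines("99999999 [", paste0(stem, ".ann"))
  expect_error(load_record(paste0(stem, ".hea"), format = "wfdb"),
               "annotation")
})

test_that("truncation arithmetic matches the stated record lengths", {
  # 25.5 h at 128 Hz truncated to 35 min -> 268,800 samples
  long <- ecg_record("nsr", rep(0.1, 25.5 * 3600 * 128), fs = 128)
  expect_equal(length(truncate_record(long)$samples), 35 * 60 * 128)
  # one minute at 128 Hz -> 7,680 samples
  expect_equal(length(truncate_record(long, max_minutes = 1)$samples), 7680)
  # already short -> unchanged
  short <- ecg_record("s", rep(0.1, 1000), fs = 128)
  expect_identical(truncate_record(short), short)
  # onset beyond the cut is dropped and the record reverts to normal
  pre <- ecg_record("p", rep(0.1, 40 * 60 * 128), fs = 128,
                    source_class = "pre_vtvf", onset_sample = 37 * 60 * 128)
  cut <- truncate_record(pre)
  expect_null(cut$onset_sample)
  expect_equal(cut$source_class, "normal")
})

test_that("outlier replacement removes spikes, is idempotent, and leaves clean signals alone", {
  fs <- 128
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t)
  rec <- ecg_record("c", x, fs)
  expect_equal(replace_outliers(rec)$samples, x)

  spiked <- x
  spiked[500] <- 50 * max(abs(x))
  spike_rec <- ecg_record("s", spiked, fs)
  fixed <- replace_outliers(spike_rec)
  expect_equal(fixed$samples[500], fixed$samples[499])
  expect_equal(fixed$samples[-500], x[-500])
  # idempotent
  expect_equal(replace_outliers(fixed)$samples, fixed$samples)
  # constant signal: MAD 0 handled as no outliers
  const <- ecg_record("k", rep(1.5, 2000), fs)
  expect_equal(replace_outliers(const)$samples, rep(1.5, 2000))
})

test_that("segmentation yields full one-minute windows and excludes onset-overlapping segments", {
  # 35-min normal record at 250 Hz -> 35 segments of 15,000 samples
  rec <- ecg_record("n", rep(0.1, 35 * 60 * 250), fs = 250)
  segs <- segment_record(rec)
  expect_length(segs, 35)
  expect_true(all(vapply(segs, function(s) length(s$samples), numeric(1)) ==
                    15000))
  expect_true(all(vapply(segs, `[[`, integer(1), "label") == 0L))
  # concatenating normal segments reproduces the signal exactly
  expect_identical(unlist(lapply(segs, `[[`, "samples")), rec$samples)

  # onset exactly at the start of segment 30: segments 0-29 retained
  pre <- ecg_record("p", rep(0.1, 35 * 60 * 250), fs = 250,
                    source_class = "pre_vtvf", onset_sample = 30L * 60L * 250L)
  psegs <- segment_record(pre)
  expect_length(psegs, 30)
  expect_equal(max(vapply(psegs, `[[`, integer(1), "index_in_record")), 29L)
  # minutes_before_onset measured from segment end
  mbo <- vapply(psegs, `[[`, numeric(1), "minutes_before_onset")
  expect_equal(mbo, seq(29, 0))
  # no retained positive segment overlaps the onset sample
  ends <- (vapply(psegs, `[[`, integer(1), "index_in_record") + 1) * 15000
  expect_true(all(ends <= pre$onset_sample))

  # degenerate: sub-minute record
  expect_warning(out <- segment_record(ecg_record("t", rep(0, 59 * 250), 250)),
                 "shorter")
  expect_length(out, 0)
})

test_that("feature tables round-trip and reject missing columns", {
  tab <- synth_dataset(5, effect = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), 10)
  for (f in feature_names())
    expect_equal(signif(back[[f]], 6), signif(tab[[f]], 6))

  broken <- tab[, setdiff(names(tab), "sdRamp")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, path2, row.names = FALSE)
  expect_error(read_feature_table(path2), "sdRamp")
  expect_error(write_feature_table(broken, path2), "sdRamp")

  # a column map resolves non-canonical headers
  renamed <- tab
  names(renamed)[names(renamed) == "mRR"] <- "mean_rr_s"
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(renamed, path3, row.names = FALSE)
  mapped <- read_feature_table(path3, column_map = c(mRR = "mean_rr_s"))
  expect_equal(mapped$mRR, tab$mRR)
})

test_that("the curated study roster has nine records per database", {
  roster <- study_record_roster()
  expect_equal(nrow(roster), 18)
  expect_equal(sum(roster$source_class == "pre_vtvf"), 9)
  expect_equal(sum(roster$source_class == "normal"), 9)
  expect_true(all(roster$fs[roster$database == "NSRDB"] == 128))
  expect_true(all(roster$fs[roster$database == "VFDB"] == 250))
})
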