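test_that("RR intervals are plain first differences in seconds", {
  expect_equal(rr_intervals(c(0L, 128L, 256L), fs = 128), c(1, 1))
  expect_equal(rr_intervals(c(0L, 64L), fs = 128), 0.5)
  expect_warning(out <- rr_intervals(c(10L), fs = 128), "fewer")
  expect_length(out, 0)
  set.seed(42)
  idx <- cumsum(sample(50:150, 40, replace = TRUE))
  expect_equal(rr_intervals(idx, fs = 250), diff(idx) / 250)
})

test_that("HR, mRR, RMSSD and SDNN match hand-computed values", {
  expect_equal(compute_hr(c(0.5, 0.5)), 120)
  expect_equal(compute_hr(1.0), 60)
  expect_equal(compute_hr(c(0.4, 0.6)), 120)
  expect_error(compute_hr(c(0.5, -0.1)), "data error")

  expect_equal(compute_mrr(c(0.5, 0.5)), 0.5)
  expect_equal(compute_mrr(c(0.4, 0.6)), 0.5)

  expect_equal(compute_rmssd(rep(0.8, 10)), 0)
  expect_equal(compute_rmssd(c(0.4, 0.6)), 0.2)
  expect_equal(compute_rmssd(c(0.4, 0.6, 0.4)), sqrt((0.04 + 0.04) / 2))

  expect_equal(compute_sdnn(rep(0.7, 5)), 0)
  expect_equal(compute_sdnn(c(0.4, 0.6)), 0.1)
  expect_equal(compute_sdnn(0.9), 0)
})

test_that("RR statistics equal brute-force oracles on 1,000 random sequences", {
  set.seed(7)
  for (i in seq_len(1000)) {
    m <- sample(2:40, 1)
    rr <- stats::runif(m, 0.3, 1.5)
    expect_equal(compute_mrr(rr), sum(rr) / m, tolerance = 1e-12)
    expect_equal(compute_hr(rr), 60 / (sum(rr) / m), tolerance = 1e-12)
    d <- rr[-1] - rr[-m]
    expect_equal(compute_rmssd(rr), sqrt(sum(d^2) / (m - 1)),
                 tolerance = 1e-12)
    mu <- sum(rr) / m
    expect_equal(compute_sdnn(rr), sqrt(sum((rr - mu)^2) / m),
                 tolerance = 1e-12)
  }
})

test_that("the beats-denominator variant reproduces the literal convention", {
  rr <- c(0.4, 0.6, 0.5)
  expect_equal(compute_mrr(rr, denominator = "beats"), sum(rr) / 4)
  expect_equal(compute_rmssd(rr, denominator = "beats"),
               sqrt(sum(diff(rr)^2) / 4))
  expect_equal(compute_sdnn(rr, denominator = "beats"),
               sqrt(sum((rr - mean(rr))^2) / 4))
  expect_equal(compute_hr(rr, mode = "mean_inst"), mean(60 / rr))
})

test_that("QRS amplitude features use the qon baseline and population SDs", {
  fs <- 100
  x <- numeric(1000)
  f <- data.frame(r_idx = c(100L, 300L), q_idx = c(95L, 295L),
                  s_idx = c(105L, 305L), qon_idx = c(90L, 290L),
                  soff_idx = c(108L, 310L), valid = TRUE)
  x[c(101, 301)] <- c(1.0, 1.2)        # R amplitudes, baseline 0 at qon
  out <- compute_qrs_amplitude_features(x, fs, f)
  expect_equal(out$mRamp, 1.1)
  expect_equal(out$sdRamp, 0.1)        # population SD of {1.0, 1.2}
  expect_equal(out$mQRSd, mean(c(18, 20) / fs))
  # identical beats: all SDs zero
  x2 <- x
  x2[301] <- 1.0
  f2 <- f
  f2$soff_idx <- f2$qon_idx + 18L
  out2 <- compute_qrs_amplitude_features(x2, fs, f2)
  expect_equal(out2$sdRamp, 0)
  expect_equal(out2$sdQRSd, 0)
  # a constant offset cancels through the baseline correction
  out3 <- compute_qrs_amplitude_features(x + 0.7, fs, f)
  expect_equal(out3$mRamp, out$mRamp)
  expect_equal(out3$mQamp, out$mQamp)
  # no valid beats -> segment dropped
  f_bad <- f
  f_bad$valid <- FALSE
  expect_error(compute_qrs_amplitude_features(x, fs, f_bad), "dropped")
})

test_that("a clean 60-bpm minute yields the expected feature vector", {
  g <- clean_minute(bpm = 60, fs = 250, jitter = 0, noise = 0.005, seed = 21)
  seg <- minute_segment("m", 0L, g$record$samples[1:15000], 250, label = 0L)
  fv <- extract_feature_vector(seg)
  expect_false(is.null(fv))
  expect_equal(fv$mHR, 60, tolerance = 1 / 60)
  expect_lt(fv$SDNN, 0.01)
  expect_equal(fv$mRR * fv$mHR, 60, tolerance = 1e-9)
  expect_true(fv$mQRSd > 0.060 && fv$mQRSd < 0.120)
  # determinism
  fv2 <- extract_feature_vector(seg)
  expect_identical(fv, fv2)
})

test_that("features are stable across sampling rates for the same waveform", {
  specs <- lapply(c(128, 250), function(fs)
    synth_spec(fs = fs, duration_s = 60, mean_rr = 0.8, rr_jitter_sd = 0.03,
               noise_sd = 0.005, seed = 31))
  fvs <- lapply(specs, function(sp) {
    g <- synth_ecg_record(sp)
    seg <- minute_segment("m", 0L, g$record$samples[1:round(60 * sp$fs)],
                          sp$fs, label = 0L)
    extract_feature_vector(seg)
  })
  for (f in c("mRR", "mHR", "mRamp"))
    expect_equal(fvs[[1]][[f]], fvs[[2]][[f]], tolerance = 0.05)
  # QRS duration rests on zero-slope indices quantized at the sampling
  # period (7.8 ms at 128 Hz), so its cross-rate agreement is coarser
  expect_equal(fvs[[1]]$mQRSd, fvs[[2]]$mQRSd, tolerance = 0.15)
})

test_that("RR-derived statistics are invariant to time shifts of the segment", {
  g <- clean_minute(bpm = 72, fs = 250, jitter = 0.03, noise = 0.005,
                    seed = 13)
  det <- detect_r_peaks(g$record)
  rr <- rr_intervals(det)
  shifted <- rr_intervals(r_peak_list(det$indices + 500L, 250))
  expect_equal(compute_sdnn(rr), compute_sdnn(shifted))
  expect_equal(compute_rmssd(rr), compute_rmssd(shifted))
})
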