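make_sine_record <- function(freq_hz, duration_s = 60, amp = 1, offset = 0) {
  x <- offset + amp * sin(2 * pi * freq_hz * (0:(round(125 * duration_s) - 1)) / 125)
  waveform_record("sine", setNames(rep(list(x), 6),
                                   c("PAP", "ABP", "CVP", "RESP", "PPG", "ECG")))
}

rms_mid <- function(x) {
  n <- length(x)
  sqrt(mean(x[round(n * 0.15):round(n * 0.85)]^2))
}

test_that("band-pass removes DC and leaves the cardiac band intact", {
  const <- make_sine_record(1, amp = 0, offset = 50)
  expect_lt(abs(mean(bandpass(const)$channels$PAP)), 1e-6)
  rec <- make_sine_record(10, offset = 50)
  out <- bandpass(rec)
  expect_lt(abs(mean(out$channels$PAP)), 1e-2)
  expect_equal(length(out$channels$PAP), length(rec$channels$PAP))
  # 10 Hz is deep in the passband: the designed response predicts ~unity gain
  gain_oracle <- sqrt(bandpass_response(10))
  expect_gt(gain_oracle, 0.95)
  ratio <- rms_mid(out$channels$ECG) / rms_mid(rec$channels$ECG - 50)
  expect_lt(abs(ratio - gain_oracle), 0.05)
})

test_that("a 60 Hz sinusoid is attenuated by at least 20 dB", {
  # oracle: the squared Butterworth magnitude at 60 Hz
  expect_lt(10 * log10(bandpass_response(60)), -20)
  rec <- make_sine_record(60)
  out <- bandpass(rec)
  atten_db <- 20 * log10(rms_mid(out$channels$PAP) / rms_mid(rec$channels$PAP))
  expect_lt(atten_db, -20)
})

test_that("filtering twice changes a passband sinusoid by at most the single-pass tolerance squared", {
  rec <- make_sine_record(10)
  once <- bandpass(rec)
  twice <- bandpass(once)
  r1 <- rms_mid(once$channels$PAP) / rms_mid(rec$channels$PAP)
  r2 <- rms_mid(twice$channels$PAP) / rms_mid(once$channels$PAP)
  tol1 <- abs(1 - sqrt(bandpass_response(10))) + 1e-4
  expect_lt(abs(1 - r2), max(tol1^2, 1e-6) + 1e-6)
  expect_lt(abs(r1 - r2), 1e-3)
})

test_that("too-short records are rejected by the filter", {
  rec <- waveform_record("short", setNames(rep(list(rnorm(10)), 6),
                                           c("PAP", "ABP", "CVP", "RESP", "PPG", "ECG")))
  expect_error(bandpass(rec), "too short")
})

test_that("window counts match brute-force enumeration over a random grid", {
  set.seed(71)
  sim <- quiet_record(seed = 5, duration_s = 26)
  for (i in 1:100) {
    w <- runif(1, 0.5, 5)
    s <- runif(1, 0.1, w)
    dur <- runif(1, 6, 26)
    n_samp <- round(125 * dur)
    rec <- sim$record
    rec$channels <- lapply(rec$channels, `[`, seq_len(n_samp))
    rec$quality_mask <- rec$quality_mask[seq_len(n_samp)]
    got <- segment(rec, w, s)
    expect_equal(length(got$subject_ids), count_windows_bruteforce(n_samp, w, s))
  }
})

test_that("segmentation endpoints and alignment behave as specified", {
  sim <- quiet_record(seed = 5, duration_s = 10)
  s1 <- segment(sim$record, 2, 0.5)
  expect_equal(length(s1$subject_ids), 17)
  s2 <- segment(sim$record, 2, 2)
  expect_equal(length(s2$subject_ids), 5)
  # window_s = record length -> exactly one window
  rec <- sim$record
  rec$channels <- lapply(rec$channels, `[`, 1:500)
  rec$quality_mask <- logical(500)
  s3 <- segment(rec, 4, 1)
  expect_equal(length(s3$subject_ids), 1)
  # channels share the same time alignment; target is PAP
  idx <- s1$start_index[3]:(s1$start_index[3] + s1$window_samples - 1)
  expect_equal(s1$target_windows[3, ], sim$record$channels$PAP[idx])
  expect_equal(s1$input_windows[3, "ECG", ], sim$record$channels$ECG[idx])
  # a sub-window record yields an empty set with a warning
  rec$channels <- lapply(rec$channels, `[`, 1:100)
  rec$quality_mask <- logical(100)
  expect_warning(s4 <- segment(rec, 2, 1), "shorter than one window")
  expect_equal(length(s4$subject_ids), 0)
})

test_that("patient-level splits partition the cohort exactly", {
  ids180 <- sprintf("P%03d", 1:180)
  sp <- split_by_patient(ids180, seed = 1)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 144, val = 18, test = 18))
  sp10 <- split_by_patient(sprintf("P%02d", 1:10), seed = 1)
  expect_equal(lengths(sp10[c("train", "val", "test")]),
               c(train = 8, val = 1, test = 1))
  expect_identical(split_by_patient(ids180, seed = 7),
                   split_by_patient(ids180, seed = 7))
  set.seed(5)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    ids <- sprintf("S%04d", sample(9999, n))
    sp <- split_by_patient(ids, seed = i)
    expect_setequal(unlist(sp), ids)
    expect_length(intersect(sp$train, sp$val), 0)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$val, sp$test), 0)
  }
  expect_error(split_by_patient(c("a", "b")), "at least 3")
})
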