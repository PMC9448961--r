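test_that("noiseless unmodulated pressure pulses hit the programmed extremes exactly", {
  p <- subject_params(heart_rate_bpm = 60, hr_sd_bpm = 0, resp_mod_frac = 0,
                      pap_sys_mmHg = 40, pap_dia_mmHg = 20, noise_sd = 0)
  sim <- simulate_record(p, 60)
  expect_equal(length(sim$truth$beat_times_s), 60)
  expect_true(all(sim$truth$per_beat_sbp_mmHg$PAP == 40))
  expect_true(all(sim$truth$per_beat_dbp_mmHg$PAP == 20))
  expect_equal(length(sim$record$channels$ECG), round(125 * 60))
  expect_named(sim$record$channels, c("PAP", "ABP", "CVP", "RESP", "PPG", "ECG"))
})

test_that("respiratory modulation bounds the per-beat maxima", {
  p <- subject_params(resp_mod_frac = 0.1, noise_sd = 0, pap_sys_mmHg = 40,
                      pap_dia_mmHg = 20, seed = 3)
  sim <- simulate_record(p, 30)
  sbp <- sim$truth$per_beat_sbp_mmHg$PAP
  expect_true(all(sbp >= 0.9 * 40 & sbp <= 1.1 * 40))
})

test_that("ground truth equals per-beat extrema recomputed from the noiseless signal", {
  for (seed in 1:5) {
    p <- subject_params(resp_mod_frac = 0.08, noise_sd = 0, hr_sd_bpm = 3,
                        seed = seed)
    sim <- simulate_record(p, 25)
    pap <- sim$record$channels$PAP
    bt <- sim$truth$beat_times_s
    t <- (seq_along(pap) - 1) / 125
    ends <- c(bt[-1], max(t) + 1)
    for (ch in c("PAP", "ABP", "CVP")) {
      x <- sim$record$channels[[ch]]
      sbp <- vapply(seq_along(bt), function(i) max(x[t >= bt[i] & t < ends[i]]), 0)
      expect_equal(sim$truth$per_beat_sbp_mmHg[[ch]], sbp, tolerance = 1e-14)
    }
  }
})

test_that("beat count tracks rate times duration within one edge beat", {
  for (hr in c(50, 75, 110)) {
    sim <- simulate_record(subject_params(heart_rate_bpm = hr, hr_sd_bpm = 0,
                                          noise_sd = 0), 40)
    expect_lte(abs(length(sim$truth$beat_times_s) - floor(40 * hr / 60)), 1)
  }
})

test_that("records are deterministic given a seed and differ across seeds", {
  a <- simulate_record(subject_params(seed = 9, noise_sd = 0.3), 10)
  b <- simulate_record(subject_params(seed = 9, noise_sd = 0.3), 10)
  expect_identical(a$record$channels, b$record$channels)
  expect_identical(a$truth, b$truth)
  c1 <- simulate_cohort(3, duration_s = 8, seed = 1)
  c2 <- simulate_cohort(3, duration_s = 8, seed = 1)
  c3 <- simulate_cohort(3, duration_s = 8, seed = 2)
  expect_identical(lapply(c1, `[[`, "truth"), lapply(c2, `[[`, "truth"))
  expect_false(identical(lapply(c1, function(s) s$truth$beat_times_s),
                         lapply(c3, function(s) s$truth$beat_times_s)))
})

test_that("degenerate cohort ranges pin the drawn parameters", {
  r <- default_param_ranges()
  r$heart_rate_bpm <- c(80, 80)
  r$pap_sys_mmHg <- c(45, 45)
  r$pap_dia_mmHg <- c(20, 20)
  co <- simulate_cohort(1, duration_s = 8, param_ranges = r, seed = 4)
  expect_equal(co[[1]]$params$heart_rate_bpm, 80)
  expect_equal(co[[1]]$params$pap_sys_mmHg, 45)
})

test_that("invalid parameters and too-short durations are rejected", {
  expect_error(subject_params(pap_sys_mmHg = 20, pap_dia_mmHg = 30), "pap_sys")
  expect_error(subject_params(resp_mod_frac = 0.6), "resp_mod_frac")
  expect_error(simulate_record(subject_params(heart_rate_bpm = 60), 1.5),
               "two beats")
  expect_error(simulate_cohort(2, param_ranges = list()), "non-empty")
  expect_error(simulate_cohort(2, param_ranges = list(heart_rate_bpm = c(90, 80))),
               "invalid ranges")
})

test_that("ground truth writer emits one row per beat", {
  sim <- quiet_record(seed = 2, duration_s = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sim$truth, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(df), length(sim$truth$beat_times_s))
  expect_true(all(c("time_s", "pap_sbp", "pap_dbp") %in% names(df)))
})
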