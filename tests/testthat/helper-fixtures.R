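# Shared fixtures and independent oracles, all built in code.

# cohort ranges with every amplitude parameter fixed and no modulation or
# noise: PAP is then a deterministic function of the beat/respiration state
# shared with the noninvasive channels
noiseless_ranges <- function() {
  r <- default_param_ranges()
  for (f in c("pap_sys_mmHg", "pap_dia_mmHg", "abp_sys_mmHg", "abp_dia_mmHg",
              "cvp_mean_mmHg", "ppg_delay_s")) {
    r[[f]] <- rep(mean(r[[f]]), 2)
  }
  r$resp_mod_frac <- c(0, 0)
  r$noise_sd <- c(0, 0)
  r
}

# independent frequency-domain MODWT: circular filtering expressed through
# DFT-domain transfer functions instead of the time-domain pyramid
modwt_fft_oracle <- function(x, level = 6L) {
  n <- length(x)
  g <- papwave:::SYM4_DEC_LO / sqrt(2)
  h <- papwave:::SYM4_DEC_HI / sqrt(2)
  f <- (seq_len(n) - 1) / n
  tf <- function(filt, scale) {
    # DFT of the filter upsampled by `scale` (circular)
    sapply(f, function(fk) sum(filt * exp(-2i * pi * fk * scale * (seq_along(filt) - 1))))
  }
  X <- stats::fft(x)
  bands <- matrix(0, level + 1L, n)
  G_cum <- rep(1 + 0i, n)
  for (j in seq_len(level)) {
    Hj <- tf(h, 2^(j - 1)) * G_cum
    bands[j, ] <- Re(stats::fft(Hj * X, inverse = TRUE)) / n
    G_cum <- G_cum * tf(g, 2^(j - 1))
  }
  bands[level + 1L, ] <- Re(stats::fft(G_cum * X, inverse = TRUE)) / n
  bands
}

# brute-force window count: enumerate every admissible start index
count_windows_bruteforce <- function(n_samples, window_s, step_s, fs = 125) {
  ws <- round(fs * window_s)
  ss <- round(fs * step_s)
  start <- 1L
  count <- 0L
  while (start + ws - 1L <= n_samples) {
    count <- count + 1L
    start <- start + ss
  }
  count
}

# quick single-subject noiseless record for beat-level tests
quiet_record <- function(seed = 1, duration_s = 20, hr = 75, hr_sd = 2) {
  simulate_record(subject_params(heart_rate_bpm = hr, hr_sd_bpm = hr_sd,
                                 resp_mod_frac = 0, noise_sd = 0, seed = seed),
                  duration_s)
}
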