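# Synthetic coupled-hemodynamics simulator: six bedside channels on a common
# 125 Hz grid, driven by one latent beat/respiration state, with exact
# per-beat ground truth.

PW_FS <- 125

# pulse morphology constants: raised-cosine upstroke over the first 30% of
# the cycle, exponential decay (rate 4) back toward the diastolic level
PW_UPSTROKE_FRAC <- 0.3
PW_DECAY_RATE <- 4

#' Subject-level simulation parameters
#'
#' Bundles the physiological parameters of one simulated subject. Defaults
#' are typical ICU vitals for a pulmonary-artery-catheter cohort (heart rate
#' near 89 bpm, PAP near 42/22 mmHg, systemic ABP near 117/60 mmHg).
#'
#' @param heart_rate_bpm mean heart rate, beats/min.
#' @param hr_sd_bpm beat-to-beat SD of the instantaneous rate, beats/min.
#' @param resp_rate_bpm respiratory rate, breaths/min.
#' @param pap_sys_mmHg,pap_dia_mmHg per-beat pulmonary artery pressure
#'   extremes, mmHg (`pap_sys_mmHg > pap_dia_mmHg > 0`).
#' @param abp_sys_mmHg,abp_dia_mmHg per-beat arterial pressure extremes, mmHg.
#' @param cvp_mean_mmHg mean central venous pressure, mmHg.
#' @param ppg_delay_s pulse-arrival lag of the PPG upstroke after the ECG
#'   R peak, seconds.
#' @param resp_mod_frac fractional amplitude modulation of the pressure
#'   channels by respiration, in `[0, 0.5)`.
#' @param noise_sd additive white Gaussian noise SD applied to every channel
#'   (in that channel's units).
#' @param seed integer RNG seed; the record is fully determined by the
#'   parameters and this seed.
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(heart_rate_bpm = 89, hr_sd_bpm = 2,
                           resp_rate_bpm = 18,
                           pap_sys_mmHg = 42, pap_dia_mmHg = 22,
                           abp_sys_mmHg = 117, abp_dia_mmHg = 60,
                           cvp_mean_mmHg = 8, ppg_delay_s = 0.2,
                           resp_mod_frac = 0.05, noise_sd = 0,
                           seed = 1L) {
  p <- list(heart_rate_bpm = heart_rate_bpm, hr_sd_bpm = hr_sd_bpm,
            resp_rate_bpm = resp_rate_bpm,
            pap_sys_mmHg = pap_sys_mmHg, pap_dia_mmHg = pap_dia_mmHg,
            abp_sys_mmHg = abp_sys_mmHg, abp_dia_mmHg = abp_dia_mmHg,
            cvp_mean_mmHg = cvp_mean_mmHg, ppg_delay_s = ppg_delay_s,
            resp_mod_frac = resp_mod_frac, noise_sd = noise_sd,
            seed = as.integer(seed))
  validate_subject_params(p)
  structure(p, class = "subject_params")
}

validate_subject_params <- function(p) {
  stopifnot_scalar_number(p$heart_rate_bpm, "heart_rate_bpm", lower = 20, upper = 250)
  stopifnot_scalar_number(p$hr_sd_bpm, "hr_sd_bpm", lower = 0)
  stopifnot_scalar_number(p$resp_rate_bpm, "resp_rate_bpm", lower = 2, upper = 60)
  stopifnot_scalar_number(p$ppg_delay_s, "ppg_delay_s", lower = 0, upper = 1)
  stopifnot_scalar_number(p$noise_sd, "noise_sd", lower = 0)
  if (!(p$pap_sys_mmHg > p$pap_dia_mmHg && p$pap_dia_mmHg > 0)) {
    stop("PAP parameters must satisfy pap_sys_mmHg > pap_dia_mmHg > 0", call. = FALSE)
  }
  if (!(p$abp_sys_mmHg > p$abp_dia_mmHg && p$abp_dia_mmHg > 0)) {
    stop("ABP parameters must satisfy abp_sys_mmHg > abp_dia_mmHg > 0", call. = FALSE)
  }
  if (!(p$resp_mod_frac >= 0 && p$resp_mod_frac < 0.5)) {
    stop("`resp_mod_frac` must lie in [0, 0.5)", call. = FALSE)
  }
  stopifnot_scalar_number(p$cvp_mean_mmHg, "cvp_mean_mmHg", lower = 1)
  invisible(p)
}

# single-cycle pressure/PPG pulse shape on phase phi in [0, Inf):
# 0 -> 1 raised-cosine upstroke on [0, PW_UPSTROKE_FRAC], then exponential
# decay; phases beyond 1 continue the decay (used for trailing samples)
pulse_shape <- function(phi) {
  s <- numeric(length(phi))
  up <- phi < PW_UPSTROKE_FRAC
  s[up] <- 0.5 * (1 - cos(pi * phi[up] / PW_UPSTROKE_FRAC))
  s[!up] <- exp(-PW_DECAY_RATE * (phi[!up] - PW_UPSTROKE_FRAC) / (1 - PW_UPSTROKE_FRAC))
  s
}

# Build a beat-synchronous pressure channel. Each complete beat is rescaled
# on its own sample grid so its maximum is exactly `sys` and its minimum
# exactly `dia`; lead-in and trailing samples continue the raw decay so every
# beat onset is a strict local minimum.
pulse_train <- function(onsets, rrs, sys, dia, n, fs) {
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  # lead-in: tail of a virtual beat ending at the first onset
  pre <- t < onsets[1]
  if (any(pre)) {
    phi <- (t[pre] - (onsets[1] - rrs[1])) / rrs[1]
    x[pre] <- dia + (sys - dia) * pulse_shape(pmax(phi, PW_UPSTROKE_FRAC))
  }
  for (i in seq_along(onsets)) {
    t_end <- if (i < length(onsets)) onsets[i + 1] else onsets[i] + rrs[i]
    j <- which(t >= onsets[i] & t < t_end)
    if (!length(j)) next
    s <- pulse_shape((t[j] - onsets[i]) / rrs[i])
    rng <- range(s)
    if (rng[2] > rng[1]) {
      x[j] <- dia + (sys - dia) * (s - rng[1]) / (rng[2] - rng[1])
    } else {
      x[j] <- dia
    }
  }
  # trailing samples beyond the last cycle: continue the decay smoothly from
  # the last in-cycle sample, so the junction creates no spurious extremum
  last_end <- onsets[length(onsets)] + rrs[length(rrs)]
  post <- which(t >= last_end)
  if (length(post) && post[1] > 1L) {
    v_end <- x[post[1] - 1L]
    rr_l <- rrs[length(rrs)]
    tau <- t[post] - t[post[1] - 1L]
    x[post] <- dia + (v_end - dia) *
      exp(-PW_DECAY_RATE * tau / ((1 - PW_UPSTROKE_FRAC) * rr_l))
  }
  x
}

# ECG beat template: sum of Gaussians (P, Q, R, S, T) with a dominant R
# deflection, amplitudes in mV
ecg_train <- function(r_times, n, fs) {
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  waves <- list(c(-0.18, 0.12, 0.030),   # P
                c(-0.025, -0.15, 0.010), # Q
                c(0.000, 1.00, 0.012),   # R
                c(0.025, -0.20, 0.010),  # S
                c(0.250, 0.30, 0.050))   # T
  for (r in r_times) {
    # only evaluate near the beat for speed
    j <- which(t >= r - 0.35 & t <= r + 0.45)
    for (w in waves) {
      x[j] <- x[j] + w[2] * exp(-0.5 * ((t[j] - r - w[1]) / w[3])^2)
    }
  }
  x
}

#' Simulate one six-channel hemodynamic record
#'
#' Generates PAP, ABP, CVP, RESP, PPG and ECG lead II on a common 125 Hz
#' grid. All channels share one latent beat process (an i.i.d. Gaussian
#' beat-to-beat rate, truncated at three SDs) and one respiratory phase;
#' pressure channels are amplitude-modulated by
#' `1 + resp_mod_frac * resp_normalized`. Per-beat systolic/diastolic ground
#' truth is computed from the noiseless pressure channels before noise is
#' added, so with `noise_sd = 0` the recorded per-beat extrema equal the
#' ground truth at machine precision.
#'
#' @param params a [subject_params()] object.
#' @param duration_s record duration in seconds (at least two beats).
#' @param subject_id subject identifier stored in the record.
#' @return a list with elements `record` (a [waveform_record()]) and `truth`
#'   (class `ground_truth`: `beat_times_s` plus per-beat SBP/DBP data frames
#'   with one column per pressure channel).
#' @export
simulate_record <- function(params, duration_s, subject_id = "synthetic") {
  if (!inherits(params, "subject_params")) params <- do.call(subject_params, params)
  validate_subject_params(params)
  min_dur <- 2 / (params$heart_rate_bpm / 60)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s < min_dur) {
    stop(sprintf("`duration_s` must cover at least two beats (>= %.2f s)", min_dur),
         call. = FALSE)
  }
  n <- round(PW_FS * duration_s)
  with_seed(params$seed, {
    # latent beat process: instantaneous rate per beat, truncated at +/- 3 SD
    max_beats <- ceiling(duration_s * (params$heart_rate_bpm + 3 * params$hr_sd_bpm) / 60) + 2L
    rate <- params$heart_rate_bpm +
      pmin(pmax(stats::rnorm(max_beats, 0, params$hr_sd_bpm %||% 0),
                -3 * params$hr_sd_bpm), 3 * params$hr_sd_bpm)
    rate <- pmax(rate, 20)
    rr <- 60 / rate
    onsets <- cumsum(c(0.4 * rr[1], rr[-length(rr)]))
    # keep beats whose systolic peak is strictly interior to the record
    peak_t <- onsets + PW_UPSTROKE_FRAC * rr
    keep <- round(peak_t * PW_FS) + 1 <= n - 1 & onsets > 0
    onsets <- onsets[keep]
    rr <- rr[keep]
    if (length(onsets) < 2L) {
      stop("duration too short: fewer than two complete beats", call. = FALSE)
    }

    t <- (seq_len(n) - 1) / PW_FS
    resp <- sin(2 * pi * params$resp_rate_bpm / 60 * t)
    mod <- 1 + params$resp_mod_frac * resp

    press <- list(
      PAP = pulse_train(onsets, rr, params$pap_sys_mmHg, params$pap_dia_mmHg, n, PW_FS) * mod,
      ABP = pulse_train(onsets, rr, params$abp_sys_mmHg, params$abp_dia_mmHg, n, PW_FS) * mod,
      CVP = pulse_train(onsets, rr, params$cvp_mean_mmHg + 2,
                        max(params$cvp_mean_mmHg - 2, 0.5), n, PW_FS) * mod
    )
    ppg <- pulse_train(onsets + params$ppg_delay_s, rr, 1, 0, n, PW_FS)
    ecg <- ecg_train(onsets, n, PW_FS)

    # per-beat ground truth from the noiseless pressures
    beat_idx <- lapply(seq_along(onsets), function(i) {
      t_end <- if (i < length(onsets)) onsets[i + 1] else onsets[i] + rr[i]
      which(t >= onsets[i] & t < pmin(t_end, duration_s))
    })
    sbp <- vapply(press, function(x) vapply(beat_idx, function(j) max(x[j]), 0), numeric(length(onsets)))
    dbp <- vapply(press, function(x) vapply(beat_idx, function(j) min(x[j]), 0), numeric(length(onsets)))
    if (length(onsets) == 1L) { sbp <- t(sbp); dbp <- t(dbp) }

    channels <- c(press, list(RESP = resp, PPG = ppg, ECG = ecg))
    if (params$noise_sd > 0) {
      channels <- lapply(channels, function(x) x + stats::rnorm(n, 0, params$noise_sd))
    }
    record <- waveform_record(subject_id, channels[c("PAP", "ABP", "CVP", "RESP", "PPG", "ECG")])
    truth <- structure(list(
      beat_times_s = onsets,
      per_beat_sbp_mmHg = as.data.frame(sbp),
      per_beat_dbp_mmHg = as.data.frame(dbp)
    ), class = "ground_truth")
    list(record = record, truth = truth, params = params)
  })
}

#' Default cohort parameter ranges
#'
#' Uniform sampling ranges (mean plus/minus one SD of typical catheterised
#' ICU cohort vitals: heart rate 89 +/- 17 bpm, PAP 42 +/- 13 over
#' 22 +/- 8 mmHg, ABP 117 +/- 23 over 60 +/- 15 mmHg, respiratory rate
#' 20 +/- 7 /min).
#'
#' @return named list of `c(min, max)` ranges per [subject_params()] field.
#' @export
default_param_ranges <- function() {
  list(heart_rate_bpm = c(72, 106), hr_sd_bpm = c(0.5, 4),
       resp_rate_bpm = c(13, 26),
       pap_sys_mmHg = c(29, 55.5), pap_dia_mmHg = c(14.4, 27.5),
       abp_sys_mmHg = c(94.3, 139.7), abp_dia_mmHg = c(45.1, 74.7),
       cvp_mean_mmHg = c(4, 12), ppg_delay_s = c(0.15, 0.3),
       resp_mod_frac = c(0, 0.1), noise_sd = c(0, 0))
}

#' Simulate a cohort of subjects
#'
#' Draws independent subject parameters uniformly from `param_ranges` and
#' simulates one record per subject. Fully reproducible given `seed`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param duration_s record duration per subject, seconds.
#' @param param_ranges named list of `c(min, max)` ranges (see
#'   [default_param_ranges()]); a degenerate range (`min == max`) fixes that
#'   parameter.
#' @param seed integer cohort seed.
#' @return list of per-subject lists `(record, truth, params)`.
#' @export
simulate_cohort <- function(n_subjects, duration_s = 30,
                            param_ranges = default_param_ranges(), seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be >= 1", call. = FALSE)
  }
  if (!is.list(param_ranges) || !length(param_ranges)) {
    stop("`param_ranges` must be a non-empty named list of c(min, max)", call. = FALSE)
  }
  bad <- vapply(param_ranges, function(r) length(r) != 2L || any(!is.finite(r)) || r[2] < r[1], TRUE)
  if (any(bad)) {
    stop("invalid ranges for: ", paste(names(param_ranges)[bad], collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    seeds <- sample.int(2^31 - 2, n_subjects)
    draws <- lapply(seq_len(n_subjects), function(i) {
      vals <- lapply(param_ranges, function(r) stats::runif(1, r[1], r[2]))
      vals$seed <- seeds[i]
      do.call(subject_params, vals)
    })
    lapply(seq_len(n_subjects), function(i) {
      simulate_record(draws[[i]], duration_s, subject_id = sprintf("S%03d", i))
    })
  })
}

#' Write per-beat ground truth as delimited text
#'
#' One row per beat: beat time plus SBP/DBP for each pressure channel.
#'
#' @param truth a `ground_truth` object from [simulate_record()].
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- data.frame(time_s = truth$beat_times_s)
  for (ch in names(truth$per_beat_sbp_mmHg)) {
    df[[paste0(tolower(ch), "_sbp")]] <- truth$per_beat_sbp_mmHg[[ch]]
    df[[paste0(tolower(ch), "_dbp")]] <- truth$per_beat_dbp_mmHg[[ch]]
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
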