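# Filtering, sliding-window segmentation and patient-level splits.

PW_BAND_LOW_HZ <- 0.5
PW_BAND_HIGH_HZ <- 50
PW_BAND_ORDER <- 4

#' Zero-phase band-pass filter a record
#'
#' Applies the same 0.5-50 Hz Butterworth band-pass (order 4, forward-
#' backward so there is no group delay between channels) to every channel.
#' The passband removes baseline wander below 0.5 Hz and monitor noise above
#' 50 Hz while leaving the cardiac band untouched.
#'
#' @param record a [waveform_record()] at 125 Hz.
#' @return the filtered record (same length, same class).
#' @export
bandpass <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  if (record$fs != PW_FS) stop("`bandpass` expects a 125 Hz record", call. = FALSE)
  n <- length(record$channels$PAP)
  if (n < 3 * 2 * PW_BAND_ORDER) {
    stop("record too short to filter (need at least 3x the filter order)", call. = FALSE)
  }
  filt <- pw_band_filter()
  record$channels <- lapply(record$channels, filtfilt_padded, filt = filt)
  record
}

# forward-backward filtering with odd-reflection edge padding, so the slow
# (0.5 Hz) pole's start-up transient decays inside the pad, not the signal
filtfilt_padded <- function(x, filt) {
  n <- length(x)
  pad <- min(n - 1L, 10L * PW_FS)
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[(pad + 1):(pad + n)]
}

pw_band_filter <- function() {
  signal::butter(PW_BAND_ORDER,
                 c(PW_BAND_LOW_HZ, PW_BAND_HIGH_HZ) / (PW_FS / 2),
                 type = "pass")
}

#' Magnitude response of the band-pass stage
#'
#' Two-pass (forward-backward) magnitude of the record filter at the given
#' frequencies; used to derive attenuation expectations.
#'
#' @param freq_hz frequencies in Hz.
#' @return magnitude (linear scale) of the zero-phase filter at `freq_hz`.
#' @export
bandpass_response <- function(freq_hz) {
  filt <- pw_band_filter()
  w <- pi * freq_hz / (PW_FS / 2)
  h <- vapply(w, function(wk) {
    z <- exp(-1i * wk * (seq_along(filt$b) - 1))
    num <- sum(filt$b * z)
    den <- sum(filt$a * exp(-1i * wk * (seq_along(filt$a) - 1)))
    Mod(num / den)
  }, 0)
  h^2  # filtfilt applies the filter twice
}

#' Sliding-window segmentation
#'
#' Cuts a record into fixed-length windows advanced by a fixed step, in
#' index units (`window_samples = round(125 * window_s)`, start indices at
#' multiples of `round(125 * step_s)`), so no float drift accumulates. The
#' target of every window is the PAP channel; `input_signals` selects which
#' channels form the model input (the noninvasive set RESP/PPG/ECG or the
#' full five-channel set). Windows overlapping samples flagged in the
#' record's quality mask are dropped.
#'
#' @param record a [waveform_record()].
#' @param window_s window length, seconds, in `[0.5, 5]`.
#' @param step_s step length, seconds, in `[0.1, window_s]`.
#' @param input_signals character vector of input channels (default the
#'   three noninvasive ones).
#' @return a `window_set`: arrays `input_windows`
#'   (`n_windows x n_signals x window_samples`) and `target_windows`
#'   (`n_windows x window_samples`), plus per-window subject ids and start
#'   indices.
#' @export
segment <- function(record, window_s, step_s,
                    input_signals = c("RESP", "PPG", "ECG")) {
  stopifnot(inherits(record, "waveform_record"))
  stopifnot_scalar_number(window_s, "window_s", lower = 0.5, upper = 5)
  stopifnot_scalar_number(step_s, "step_s", lower = 0.1, upper = window_s)
  bad <- setdiff(input_signals, PW_CHANNELS)
  if (length(bad)) stop("unknown input signals: ", paste(bad, collapse = ", "), call. = FALSE)
  ws <- round(PW_FS * window_s)
  ss <- round(PW_FS * step_s)
  n <- length(record$channels$PAP)
  if (n < ws) {
    warning("record shorter than one window; returning empty window set")
    starts <- integer(0)
  } else {
    n_win <- (n - ws) %/% ss + 1L
    starts <- (seq_len(n_win) - 1L) * ss + 1L
  }
  # drop windows touching masked samples
  if (length(starts) && any(record$quality_mask)) {
    cm <- cumsum(record$quality_mask)
    nbad <- cm[starts + ws - 1L] - c(0, cm)[starts]
    starts <- starts[nbad == 0]
  }
  k <- length(starts)
  inputs <- array(0, dim = c(k, length(input_signals), ws),
                  dimnames = list(NULL, input_signals, NULL))
  targets <- array(0, dim = c(k, ws))
  for (i in seq_len(k)) {
    idx <- starts[i]:(starts[i] + ws - 1L)
    for (s in seq_along(input_signals)) {
      inputs[i, s, ] <- record$channels[[input_signals[s]]][idx]
    }
    targets[i, ] <- record$channels$PAP[idx]
  }
  structure(list(window_s = window_s, step_s = step_s,
                 window_samples = ws,
                 signals = input_signals,
                 input_windows = inputs, target_windows = targets,
                 subject_ids = rep(record$subject_id, k),
                 start_index = starts),
            class = "window_set")
}

#' Combine window sets from several records
#'
#' @param ... `window_set` objects (or one list of them) with identical
#'   window/step/signal configuration.
#' @return one pooled `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "window_set")) sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, TRUE, "window_set")))
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (s$window_samples != ref$window_samples ||
        !identical(s$signals, ref$signals)) {
      stop("window sets have incompatible configurations", call. = FALSE)
    }
  }
  inputs <- do.call(abind_first, lapply(sets, `[[`, "input_windows"))
  targets <- do.call(rbind, lapply(sets, `[[`, "target_windows"))
  structure(list(window_s = ref$window_s, step_s = ref$step_s,
                 window_samples = ref$window_samples, signals = ref$signals,
                 input_windows = inputs, target_windows = targets,
                 subject_ids = unlist(lapply(sets, `[[`, "subject_ids")),
                 start_index = unlist(lapply(sets, `[[`, "start_index"))),
            class = "window_set")
}

# bind 3-d arrays along the first margin
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], 0L)), d[2], d[3]),
               dimnames = list(NULL, dimnames(arrs[[1]])[[2]], NULL))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1]
    if (k) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %.3g s (step %.3g s), signals: %s\n",
              length(x$subject_ids), x$window_s, x$step_s,
              paste(x$signals, collapse = ", ")))
  invisible(x)
}

#' Patient-level train/validation/test split
#'
#' Partitions subject ids into disjoint train/validation/test sets so no
#' subject contributes windows to more than one set. Validation and test
#' sizes are `round(n * fraction)`; the remainder goes to training (a
#' 180-subject cohort at 0.8/0.1/0.1 gives 144/18/18).
#'
#' @param cohort character vector of subject ids (length >= 3).
#' @param fractions numeric length 3 summing to 1 (train, validation, test).
#' @param seed integer seed for the shuffle.
#' @return list with `train`, `val`, `test` id vectors.
#' @export
split_by_patient <- function(cohort, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  cohort <- unique(as.character(cohort))
  n <- length(cohort)
  if (n < 3) stop("need at least 3 subjects to split", call. = FALSE)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    stop("`fractions` must be three non-negative numbers summing to 1", call. = FALSE)
  }
  with_seed(seed, {
    shuffled <- sample(cohort)
    at_least_one <- function(f) if (f > 0) 1L else 0L
    n_val <- max(at_least_one(fractions[2]), round(n * fractions[2]))
    n_test <- max(at_least_one(fractions[3]), round(n * fractions[3]))
    n_train <- n - n_val - n_test
    if (n_train < 1 || n_val < 1 || n_test < 1) {
      stop("fractions leave an empty partition for this cohort size", call. = FALSE)
    }
    list(train = sort(shuffled[seq_len(n_train)]),
         val = sort(shuffled[n_train + seq_len(n_val)]),
         test = sort(shuffled[n_train + n_val + seq_len(n_test)]))
  })
}
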