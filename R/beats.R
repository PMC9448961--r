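# Per-beat systolic/diastolic pressure extraction constrained by the ECG
# beat count.

#' Detect QRS complexes
#'
#' Energy-threshold QRS detector in the Pan-Tompkins family: band-limit to
#' the QRS band (5-15 Hz), differentiate, square, integrate over a 150 ms
#' moving window, then threshold at a fixed fraction of the integrated
#' signal's peak (amplitude-normalized, so rescaling the ECG does not change
#' the detections) with a 200 ms refractory period. Each detection is
#' refined to the largest absolute band-limited deflection within 100 ms.
#'
#' @param ecg numeric ECG series (lead II), at least 2 s.
#' @param fs sampling rate, must be 125 Hz.
#' @return integer vector of R-peak sample indices (1-based, strictly
#'   increasing); empty (with a warning) for flat or non-finite input.
#' @export
detect_qrs <- function(ecg, fs = 125) {
  if (fs != PW_FS) stop("`detect_qrs` expects fs = 125", call. = FALSE)
  if (length(ecg) < 2 * fs) stop("ECG must be at least 2 s long", call. = FALSE)
  if (anyNA(ecg) || !all(is.finite(ecg)) || stats::sd(ecg) == 0) {
    warning("flat or non-finite ECG; no beats detected")
    return(integer(0))
  }
  bp <- signal::filtfilt(signal::butter(2, c(5, 15) / (fs / 2), "pass"), ecg)
  energy <- c(0, diff(bp))^2
  win <- round(0.15 * fs)
  integ <- stats::filter(energy, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- 0.2 * max(integ)
  refractory <- round(0.2 * fs)
  above <- integ > thr
  cand <- which(above & c(TRUE, integ[-1] >= integ[-length(integ)]) &
                  c(integ[-length(integ)] > integ[-1], TRUE))
  if (!length(cand)) return(integer(0))
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refractory) {
      peaks <- c(peaks, i)
      last <- i
    } else if (integ[i] > integ[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i   # keep the stronger of two close candidates
      last <- i
    }
  }
  # refine to the dominant band-limited deflection within +/- 100 ms
  half <- round(0.1 * fs)
  refined <- vapply(peaks, function(i) {
    j <- max(1, i - half):min(length(bp), i + half)
    j[which.max(abs(bp[j]))]
  }, 0L)
  sort(unique(refined))
}

#' Find strict local extrema
#'
#' Peaks are strict local maxima and valleys strict local minima of the
#' series; plateaus that form an extremum are reported once, at their
#' leftmost sample. Record boundaries are never extrema.
#'
#' @param x numeric series, length >= 3.
#' @return list with integer vectors `peaks` and `valleys` (1-based).
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) stop("series must have at least 3 samples", call. = FALSE)
  # compress plateaus to single points; an extremal run is reported at its
  # leftmost sample
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(list(peaks = integer(0), valleys = integer(0)))
  starts <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  mid <- 2:(k - 1L)
  is_peak <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]
  is_valley <- v[mid] < v[mid - 1L] & v[mid] < v[mid + 1L]
  list(peaks = starts[mid][is_peak], valleys = starts[mid][is_valley])
}

#' Extract per-beat systolic and diastolic pressures
#'
#' Given a PAP (or other pressure) segment and the beat count from the ECG,
#' selects the `n_beats` highest peaks as the systolic pressures and the
#' `n_beats` lowest valleys as the diastolic pressures, each re-sorted into
#' time order. If the waveform offers fewer extrema than beats, all
#' available ones are returned with a count-mismatch warning.
#'
#' @param pap numeric pressure series, mmHg.
#' @param n_beats beat count (>= 1), typically `length(detect_qrs(ecg))`.
#' @return object of class `beat_pressures`: `sbp_mmHg`, `dbp_mmHg`,
#'   `peak_indices`, `valley_indices`.
#' @export
extract_sbp_dbp <- function(pap, n_beats) {
  if (!is.numeric(n_beats) || n_beats < 1) {
    stop("`n_beats` must be >= 1", call. = FALSE)
  }
  n_beats <- as.integer(n_beats)
  ex <- find_extrema(pap)
  if (length(ex$peaks) < n_beats || length(ex$valleys) < n_beats) {
    warning(sprintf("found %d peaks / %d valleys for %d beats; returning all available",
                    length(ex$peaks), length(ex$valleys), n_beats))
  }
  top_peaks <- ex$peaks[order(-pap[ex$peaks], ex$peaks)][seq_len(min(n_beats, length(ex$peaks)))]
  low_valleys <- ex$valleys[order(pap[ex$valleys], ex$valleys)][seq_len(min(n_beats, length(ex$valleys)))]
  top_peaks <- sort(top_peaks)
  low_valleys <- sort(low_valleys)
  structure(list(sbp_mmHg = pap[top_peaks], dbp_mmHg = pap[low_valleys],
                 peak_indices = top_peaks, valley_indices = low_valleys),
            class = "beat_pressures")
}

#' @export
print.beat_pressures <- function(x, ...) {
  cat(sprintf("<beat_pressures> %d systolic / %d diastolic values\n",
              length(x$sbp_mmHg), length(x$dbp_mmHg)))
  invisible(x)
}
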