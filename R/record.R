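# WaveformRecord container and record I/O (delimited columnar format plus a
# minimal WFDB format-16 reader).

PW_CHANNELS <- c("PAP", "ABP", "CVP", "RESP", "PPG", "ECG")

PW_UNITS <- c(PAP = "mmHg", ABP = "mmHg", CVP = "mmHg",
              RESP = "arb", PPG = "arb", ECG = "mV")

#' Six-channel waveform record
#'
#' Container for one subject's synchronized bedside channels (PAP, ABP, CVP,
#' RESP, PPG, ECG lead II) on a fixed 125 Hz grid. A logical quality mask
#' marks samples that were missing in the source and were filled by
#' interpolation; segmentation drops windows touching masked samples.
#'
#' @param subject_id subject identifier.
#' @param channels named list with the six channels, equal lengths.
#' @param units named character vector of units (defaults: mmHg for
#'   pressures, mV for ECG, arbitrary for PPG/RESP).
#' @param quality_mask logical vector, `TRUE` where a sample is unreliable.
#' @return object of class `waveform_record`.
#' @export
waveform_record <- function(subject_id, channels, units = PW_UNITS,
                            quality_mask = NULL) {
  missing_ch <- setdiff(PW_CHANNELS, names(channels))
  if (length(missing_ch)) {
    stop("record is missing channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  channels <- channels[PW_CHANNELS]
  lens <- vapply(channels, length, 0L)
  if (length(unique(lens)) != 1L) {
    stop("all six channels must have equal length", call. = FALSE)
  }
  n <- lens[[1]]
  if (is.null(quality_mask)) quality_mask <- logical(n)
  stopifnot(length(quality_mask) == n)
  structure(list(subject_id = as.character(subject_id), fs = PW_FS,
                 channels = channels, units = units[PW_CHANNELS],
                 quality_mask = quality_mask),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> subject %s: %d samples (%.1f s) at %d Hz\n",
              x$subject_id, length(x$channels$PAP),
              length(x$channels$PAP) / x$fs, x$fs))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (any(x$quality_mask)) {
    cat(sprintf("  %d samples flagged in quality mask\n", sum(x$quality_mask)))
  }
  invisible(x)
}

record_duration_s <- function(record) length(record$channels$PAP) / record$fs

#' Write a record in the columnar text format
#'
#' Header lines (prefixed `#`) carry subject id, sampling rate and units;
#' the body is a tab-separated table with one column per channel.
#'
#' @param record a [waveform_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id: %s", record$subject_id),
    sprintf("# fs: %d", record$fs),
    sprintf("# units: %s", paste(sprintf("%s=%s", names(record$units), record$units),
                                 collapse = ","))
  ), con)
  df <- as.data.frame(lapply(record$channels, function(x) sprintf("%.17g", x)))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_columnar_record <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  subject_id <- get_field("subject_id") %||% basename(path)
  fs <- as.numeric(get_field("fs") %||% PW_FS)
  units <- PW_UNITS
  uf <- get_field("units")
  if (!is.null(uf)) {
    kv <- strsplit(strsplit(uf, ",")[[1]], "=")
    u <- vapply(kv, `[`, "", 2)
    names(u) <- vapply(kv, `[`, "", 1)
    units[names(u)] <- u
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  missing_ch <- setdiff(PW_CHANNELS, names(df))
  if (length(missing_ch)) {
    stop("record is missing channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  finalize_record(subject_id, as.list(df[PW_CHANNELS]), fs, units)
}

# Parse a WFDB .hea header and its format-16 .dat (16-bit little-endian,
# sample-interleaved) signal file.
read_wfdb_record <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("cannot read WFDB header: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3) stop("malformed WFDB header: ", hea, call. = FALSE)
  name <- rec[1]; n_sig <- as.integer(rec[2]); fs <- as.numeric(rec[3])
  n_samp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lines[1 + seq_len(n_sig)]
  parse_sig <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    fmt <- f[2]
    if (!grepl("^16", fmt)) {
      stop("only WFDB format 16 is supported (got ", fmt, ")", call. = FALSE)
    }
    gainfield <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", gainfield))
    baseline <- if (grepl("\\(", gainfield)) {
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gainfield))
    } else 0
    units <- if (grepl("/", gainfield)) sub(".*/", "", gainfield) else "adu"
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = baseline, units = units, desc = desc)
  }
  sigs <- lapply(sig, parse_sig)
  dat <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(dat)) stop("cannot read WFDB signal file: ", dat, call. = FALSE)
  raw <- readBin(dat, "integer", n = file.size(dat) / 2, size = 2,
                 signed = TRUE, endian = "little")
  n_avail <- length(raw) %/% n_sig
  if (is.na(n_samp) || n_samp <= 0 || n_samp > n_avail) n_samp <- n_avail
  mat <- matrix(raw[seq_len(n_samp * n_sig)], nrow = n_sig)
  # map signal descriptions onto the six canonical channels
  canon <- function(desc) {
    d <- toupper(desc)
    if (grepl("PAP", d)) "PAP"
    else if (grepl("ABP|ART", d)) "ABP"
    else if (grepl("CVP", d)) "CVP"
    else if (grepl("RESP", d)) "RESP"
    else if (grepl("PLETH|PPG", d)) "PPG"
    else if (grepl("ECG|\\bII\\b|LEAD", d)) "ECG"
    else NA_character_
  }
  ch_names <- vapply(sigs, function(s) canon(paste(s$desc, s$units)), "")
  channels <- list()
  units <- PW_UNITS
  for (i in seq_len(n_sig)) {
    if (is.na(ch_names[i]) || ch_names[i] %in% names(channels)) next
    channels[[ch_names[i]]] <- (mat[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
    if (sigs[[i]]$units != "adu") units[ch_names[i]] <- sigs[[i]]$units
  }
  missing_ch <- setdiff(PW_CHANNELS, names(channels))
  if (length(missing_ch)) {
    stop("record is missing channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  finalize_record(name, channels[PW_CHANNELS], fs, units)
}

# Build the quality mask from NA runs, interpolate across them, and
# resample to the 125 Hz grid if the source rate differs (zero-phase
# antialias filter followed by interpolation on the shared time axis, so no
# group delay is introduced between channels).
finalize_record <- function(subject_id, channels, fs, units) {
  n_old <- length(channels[[1]])
  mask <- Reduce(`|`, lapply(channels, is.na))
  if (any(mask)) {
    channels <- lapply(channels, function(x) {
      if (anyNA(x)) {
        ok <- which(!is.na(x))
        if (length(ok) >= 2) {
          x <- stats::approx(ok, x[ok], xout = seq_len(n_old), rule = 2)$y
        } else {
          x[is.na(x)] <- 0
        }
      }
      x
    })
  }
  if (fs != PW_FS) {
    t_old <- (seq_len(n_old) - 1) / fs
    n_new <- round(n_old * PW_FS / fs)
    t_new <- (seq_len(n_new) - 1) / PW_FS
    antialias <- if (fs > PW_FS) {
      signal::butter(4, 0.9 * (PW_FS / 2) / (fs / 2), type = "low")
    } else NULL
    channels <- lapply(channels, function(x) {
      if (!is.null(antialias)) {
        pad <- min(n_old - 1L, 4L * round(fs))
        xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n_old] - x[(n_old - 1):(n_old - pad)])
        x <- signal::filtfilt(antialias, xp)[(pad + 1):(pad + n_old)]
      }
      stats::approx(t_old, x, xout = t_new, rule = 2)$y
    })
    mask <- stats::approx(t_old, as.numeric(mask), xout = t_new,
                          method = "constant", rule = 2)$y > 0
  }
  waveform_record(subject_id, channels, units, quality_mask = mask)
}

#' Read a waveform record
#'
#' Reads one six-channel record either from the package's delimited columnar
#' format or from a WFDB header/signal pair (format 16). Signals sampled at a
#' rate other than 125 Hz are resampled to 125 Hz; runs of missing values are
#' interpolated and flagged in the record's quality mask.
#'
#' @param path path to the columnar file or the WFDB `.hea` header (with or
#'   without extension).
#' @param format `"columnar"` or `"wfdb"`.
#' @return a [waveform_record()].
#' @export
read_record <- function(path, format = c("columnar", "wfdb")) {
  format <- match.arg(format)
  if (format == "columnar" && !file.exists(path)) {
    stop("cannot read record: ", path, call. = FALSE)
  }
  switch(format,
         columnar = read_columnar_record(path),
         wfdb = read_wfdb_record(path))
}
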