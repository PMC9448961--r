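# Waveform- and beat-level performance metrics with bootstrap confidence
# intervals.

#' Waveform regression metrics
#'
#' Standard definitions: `r2 = 1 - SS_res / SS_tot`;
#' `ev = 1 - Var(y_true - y_pred) / Var(y_true)` (explained variance ignores
#' systematic bias, so `r2 <= ev` always); `mse`/`mae` are mean squared and
#' absolute errors; `mape` is the mean of `|error| / |y_true|` as a
#' percentage, excluding (with a warning) samples where `y_true` is zero.
#'
#' @param y_true,y_pred equal-length numeric vectors (concatenated PAP
#'   samples), length >= 2.
#' @return object of class `metric_report` with fields `r2`, `mse`, `mae`,
#'   `mape`, `ev` and sample count `n`.
#' @export
waveform_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (length(y_true) < 2) stop("need at least 2 samples", call. = FALSE)
  if (stats::var(y_true) == 0) {
    stop("`y_true` is constant; r2 and ev are undefined", call. = FALSE)
  }
  resid <- y_true - y_pred
  r2 <- 1 - sum(resid^2) / sum((y_true - mean(y_true))^2)
  ev <- 1 - stats::var(resid) / stats::var(y_true)
  nz <- y_true != 0
  if (!all(nz)) warning("zero values in y_true excluded from MAPE")
  mape <- 100 * mean(abs(resid[nz]) / abs(y_true[nz]))
  structure(list(r2 = r2, mse = mean(resid^2), mae = mean(abs(resid)),
                 mape = mape, ev = ev, n = length(y_true)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("r2 = %.4f  mse = %.4g  mae = %.4g  mape = %.4g%%  ev = %.4f  (n = %d)\n",
              x$r2, x$mse, x$mae, x$mape, x$ev, x$n))
  invisible(x)
}

#' Per-beat blood pressure agreement
#'
#' Pairs predicted and reference per-beat pressures by time order and
#' reports: MD (mean difference, pred - true), MAD (mean absolute
#' difference), MAPD (mean absolute percentage difference), SD (standard
#' deviation of the differences) and CP5 (percentage of beats within
#' 5 mmHg).
#'
#' @param true_bp,pred_bp equal-length per-beat pressure vectors, mmHg.
#' @return object of class `bp_agreement`: `mad`, `mapd`, `md`, `sd`, `cp5`.
#' @export
bp_agreement <- function(true_bp, pred_bp) {
  if (length(true_bp) != length(pred_bp)) {
    stop("per-beat lists differ in length; cannot pair beats", call. = FALSE)
  }
  if (!length(true_bp)) stop("need at least one beat", call. = FALSE)
  d <- pred_bp - true_bp
  structure(list(mad = mean(abs(d)),
                 mapd = 100 * mean(abs(d) / true_bp),
                 md = mean(d),
                 sd = if (length(d) > 1) stats::sd(d) else 0,
                 cp5 = 100 * mean(abs(d) < 5),
                 n_beats = length(d)),
            class = "bp_agreement")
}

#' @export
print.bp_agreement <- function(x, ...) {
  cat(sprintf("MAD = %.3g  MAPD = %.3g%%  MD = %.3g  SD = %.3g  CP5 = %.3g%%  (%d beats)\n",
              x$mad, x$mapd, x$md, x$sd, x$cp5, x$n_beats))
  invisible(x)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples whole windows (rows) with replacement and recomputes the metric
#' on the concatenated resample; the CI is the percentile interval of the
#' bootstrap distribution. The resampling unit can be switched to
#' individual samples or patients.
#'
#' @param y_true,y_pred matrices (`windows x samples`) or plain vectors
#'   (then `unit = "sample"` is implied).
#' @param metric one of `"r2"`, `"mse"`, `"mae"`, `"mape"`, `"ev"`.
#' @param n_reps bootstrap replications (default 20000, >= 100).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @param unit resampling unit: `"window"` (rows) or `"sample"`; with
#'   `unit = "patient"` supply `groups` mapping rows to patients.
#' @param groups optional patient id per row.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(y_true, y_pred, metric = "mse", n_reps = 20000L,
                         level = 0.95, seed = 1L,
                         unit = c("window", "sample", "patient"),
                         groups = NULL) {
  unit <- match.arg(unit)
  metric <- match.arg(metric, c("r2", "mse", "mae", "mape", "ev"))
  if (n_reps < 100) stop("`n_reps` must be >= 100", call. = FALSE)
  if (is.null(dim(y_true))) {
    y_true <- matrix(y_true, ncol = 1)
    y_pred <- matrix(y_pred, ncol = 1)
    if (unit == "window") unit <- "sample"
  }
  stopifnot(all(dim(y_true) == dim(y_pred)))
  if (unit == "sample") {
    y_true <- matrix(as.numeric(t(y_true)), ncol = 1)
    y_pred <- matrix(as.numeric(t(y_pred)), ncol = 1)
  }
  if (unit == "patient") {
    if (is.null(groups)) stop("`groups` required for patient-level resampling", call. = FALSE)
    units <- unique(groups)
  } else {
    units <- seq_len(nrow(y_true))
  }
  if (length(units) < 2) stop("need at least 2 resampling units", call. = FALSE)
  metric_fun <- function(idx) {
    yt <- as.numeric(t(y_true[idx, , drop = FALSE]))
    yp <- as.numeric(t(y_pred[idx, , drop = FALSE]))
    switch(metric,
           r2 = 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2),
           mse = mean((yt - yp)^2),
           mae = mean(abs(yt - yp)),
           mape = {
             nz <- yt != 0
             100 * mean(abs(yt[nz] - yp[nz]) / abs(yt[nz]))
           },
           ev = 1 - stats::var(yt - yp) / stats::var(yt))
  }
  with_seed(seed, {
    stats_boot <- vapply(seq_len(n_reps), function(r) {
      u <- sample(units, length(units), replace = TRUE)
      idx <- if (unit == "patient") {
        unlist(lapply(u, function(g) which(groups == g)))
      } else u
      metric_fun(idx)
    }, 0)
    alpha <- (1 - level) / 2
    as.numeric(stats::quantile(stats_boot, c(alpha, 1 - alpha), na.rm = TRUE,
                               names = FALSE, type = 7))
  })
}

#' Full metric report with bootstrap CIs
#'
#' Point estimates for all five waveform metrics plus percentile bootstrap
#' CIs at the requested level.
#'
#' @param y_true,y_pred `windows x samples` matrices.
#' @param n_reps bootstrap replications.
#' @param level confidence level.
#' @param seed RNG seed.
#' @param groups optional patient ids per window (stored as `n_patients`).
#' @return `metric_report` with `ci` (2 x 5 matrix) attached.
#' @export
metric_report_ci <- function(y_true, y_pred, n_reps = 2000L, level = 0.95,
                             seed = 1L, groups = NULL) {
  rep <- waveform_metrics(as.numeric(t(y_true)), as.numeric(t(y_pred)))
  cis <- vapply(c("r2", "mse", "mae", "mape", "ev"), function(m) {
    bootstrap_ci(y_true, y_pred, m, n_reps = n_reps, level = level, seed = seed)
  }, numeric(2))
  rownames(cis) <- c("ci_low", "ci_high")
  rep$ci <- cis
  rep$n_windows <- nrow(as.matrix(y_true))
  rep$n_patients <- if (!is.null(groups)) length(unique(groups)) else NA_integer_
  rep
}

#' Render and parse comparison report tables
#'
#' `report_tables` renders comparison rows (and optionally per-beat
#' agreement reports) as a delimited table plus an aligned human-readable
#' text block; `parse_report_table` reads the delimited rendering back into
#' a data frame (the two are inverse up to numeric formatting).
#'
#' @param comparison data frame of comparison rows (from
#'   [run_comparison()] or similar).
#' @param bp_reports optional named list of `bp_agreement` objects.
#' @param digits significant digits in the rendering.
#' @return list with `delimited` (character vector of TSV lines) and `text`
#'   (aligned lines); if `bp_reports` is empty a notice replaces that block.
#' @export
report_tables <- function(comparison, bp_reports = NULL, digits = 6) {
  if (is.null(comparison) || !nrow(comparison)) {
    stop("`comparison` must have at least one row", call. = FALSE)
  }
  fmt <- function(df) {
    out <- df
    for (j in seq_along(out)) {
      if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], digits)
    }
    out
  }
  cmp <- fmt(comparison)
  delim <- c(paste(names(cmp), collapse = "\t"),
             apply(cmp, 1, function(r) paste(trimws(r), collapse = "\t")))
  text <- utils::capture.output(print(cmp, row.names = FALSE))
  if (!is.null(bp_reports) && length(bp_reports)) {
    bp_df <- do.call(rbind, lapply(names(bp_reports), function(nm) {
      b <- bp_reports[[nm]]
      data.frame(name = nm, mad = b$mad, mapd = b$mapd, md = b$md,
                 sd = b$sd, cp5 = b$cp5)
    }))
    bp_df <- fmt(bp_df)
    delim <- c(delim, "", paste(names(bp_df), collapse = "\t"),
               apply(bp_df, 1, function(r) paste(trimws(r), collapse = "\t")))
    text <- c(text, "", utils::capture.output(print(bp_df, row.names = FALSE)))
  } else {
    text <- c(text, "", "(no per-beat agreement reports)")
  }
  list(delimited = delim, text = text)
}

#' @rdname report_tables
#' @param lines the `delimited` element of a [report_tables()] result.
#' @export
parse_report_table <- function(lines) {
  stop_at <- which(lines == "")[1]
  if (!is.na(stop_at)) lines <- lines[seq_len(stop_at - 1L)]
  utils::read.table(text = paste(lines, collapse = "\n"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
}
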