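# End-to-end orchestration: simulate -> preprocess -> features -> train ->
# predict -> extract per-beat pressures -> evaluate, from one configuration.

#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run. The configuration is
#' serializable (YAML) and its hash is stamped into all outputs.
#'
#' @param signal_set `"three"` (RESP/PPG/ECG) or `"five"`
#'   (ABP/CVP/RESP/PPG/ECG).
#' @param window_s,step_s segmentation parameters, seconds.
#' @param feature_mode `"raw"` or `"scattering"`.
#' @param model model family name from the registry.
#' @param n_subjects,duration_s simulated cohort size and record length.
#' @param fractions train/validation/test split fractions.
#' @param filter apply the 0.5-50 Hz band-pass before segmentation.
#' @param bootstrap_reps bootstrap replications for the metric CIs.
#' @param learning list of learning parameters (`dropout`, `learning_rate`,
#'   `batch_size`, `epochs`).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory (default: a fresh temporary directory).
#' @return object of class `run_config`.
#' @export
run_config <- function(signal_set = "three", window_s = 2, step_s = 1,
                       feature_mode = "scattering", model = "ridge",
                       n_subjects = 10, duration_s = 30,
                       fractions = c(0.8, 0.1, 0.1), filter = FALSE,
                       bootstrap_reps = 500, learning = list(),
                       seed = 1L, out_dir = NULL) {
  structure(list(signal_set = signal_set, window_s = window_s,
                 step_s = step_s, feature_mode = feature_mode, model = model,
                 n_subjects = n_subjects, duration_s = duration_s,
                 fractions = fractions, filter = filter,
                 bootstrap_reps = bootstrap_reps, learning = learning,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks every module precondition reachable from the configuration and
#' returns the violations as character messages (empty when valid).
#'
#' @param config a [run_config()].
#' @return character vector of violations (zero-length if none).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!config$signal_set %in% c("three", "five")) {
    add("signal_set must be 'three' or 'five'")
  }
  if (!is.numeric(config$window_s) || config$window_s < 0.5 || config$window_s > 5) {
    add(sprintf("window_s = %s outside the supported 0.5-5 s range",
                format(config$window_s)))
  }
  if (!is.numeric(config$step_s) || config$step_s < 0.1) {
    add("step_s must be at least 0.1 s")
  } else if (is.numeric(config$window_s) && config$step_s > config$window_s) {
    add(sprintf("step_s = %s exceeds window_s = %s",
                format(config$step_s), format(config$window_s)))
  }
  if (!config$feature_mode %in% c("raw", "scattering")) {
    add("feature_mode must be 'raw' or 'scattering'")
  }
  if (!config$model %in% PW_MODEL_NAMES) {
    add(sprintf("unknown model '%s'", config$model))
  }
  if (config$n_subjects < 3) add("n_subjects must be >= 3 for a patient-level split")
  if (length(config$fractions) != 3 || abs(sum(config$fractions) - 1) > 1e-8) {
    add("fractions must be three numbers summing to 1")
  }
  if (config$duration_s < 2 * config$window_s) {
    add("duration_s must cover at least two windows")
  }
  v
}

#' Run the full estimation pipeline
#'
#' Simulates a cohort, splits it at the patient level, optionally band-pass
#' filters, segments, trains the configured model on the training patients
#' (validation patients are only used for logging / model selection), then
#' on the held-out test patients: predicts PAP windows, computes the five
#' waveform metrics with bootstrap CIs, extracts per-beat SBP/DBP from the
#' predicted and observed waveforms under the ECG beat count, and writes all
#' reports (stamped with the configuration hash) into the run directory.
#' Test-patient windows are never touched before the evaluation stage.
#'
#' @param config a [run_config()].
#' @return path of the run directory, invisibly; the directory contains
#'   `metric_report.tsv`, `bp_agreement.tsv`, `report.txt`, `config.yaml`
#'   and `run.log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  }
  out_dir <- config$out_dir %||% tempfile("papwave_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, ...) {
    msg <- sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    logf(name, "start")
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed (config %s): %s",
                   name, hash, conditionMessage(e)), call. = FALSE)
    })
  }
  yaml::write_yaml(c(unclass(config)[setdiff(names(config), "out_dir")],
                     list(config_hash = hash)),
                   file.path(out_dir, "config.yaml"))

  cohort <- stage("simulate", simulate_cohort(config$n_subjects,
                                              config$duration_s,
                                              seed = config$seed))
  ids <- vapply(cohort, function(s) s$record$subject_id, "")
  split <- stage("split", split_by_patient(ids, config$fractions,
                                           seed = config$seed + 1L))
  logf("split", "train=%d val=%d test=%d", length(split$train),
       length(split$val), length(split$test))
  signals <- if (config$signal_set == "three") c("RESP", "PPG", "ECG") else
    c("ABP", "CVP", "RESP", "PPG", "ECG")

  prep <- function(which_ids) {
    recs <- lapply(cohort[ids %in% which_ids], `[[`, "record")
    if (config$filter) recs <- lapply(recs, bandpass)
    bind_window_sets(lapply(recs, segment, window_s = config$window_s,
                            step_s = config$step_s, input_signals = signals))
  }
  tr <- stage("preprocess", prep(split$train))
  va <- stage("preprocess", prep(split$val))
  logf("preprocess", "train windows=%d val windows=%d",
       length(tr$subject_ids), length(va$subject_ids))

  ws <- round(PW_FS * config$window_s)
  out_mode <- if (config$feature_mode == "scattering" && ws >= 225) {
    "modwt_coeffs"
  } else "waveform"
  spec <- model_spec(config$model, input_mode = config$feature_mode,
                     output_mode = out_mode)
  lcfg <- utils::modifyList(list(seed = config$seed + 2L), config$learning)
  model <- stage("train", train(spec, tr, va, lcfg))

  # evaluation stage: the first and only access to test-patient data
  te <- stage("preprocess_test", prep(split$test))
  pred <- stage("predict", predict_pap(model, te))
  rep <- stage("evaluate",
               metric_report_ci(te$target_windows, pred,
                                n_reps = config$bootstrap_reps,
                                seed = config$seed + 3L,
                                groups = te$subject_ids))

  # per-beat assessment on contiguous non-overlapping test windows
  bp <- stage("extract_bp", {
    test_rec <- cohort[ids %in% split$test]
    sb_t <- c(); sb_p <- c(); db_t <- c(); db_p <- c()
    for (s in test_rec) {
      rec <- s$record
      seg_t <- segment(rec, config$window_s, config$window_s, signals)
      if (!length(seg_t$subject_ids)) next
      pw <- predict_pap(model, seg_t)
      obs <- as.numeric(t(seg_t$target_windows))
      est <- as.numeric(t(pw))
      n_beats <- length(detect_qrs(rec$channels$ECG[seq_along(obs)]))
      if (n_beats < 1) next
      bt <- extract_sbp_dbp(obs, n_beats)
      bp_ <- extract_sbp_dbp(est, n_beats)
      k_s <- min(length(bt$sbp_mmHg), length(bp_$sbp_mmHg))
      k_d <- min(length(bt$dbp_mmHg), length(bp_$dbp_mmHg))
      sb_t <- c(sb_t, bt$sbp_mmHg[seq_len(k_s)]); sb_p <- c(sb_p, bp_$sbp_mmHg[seq_len(k_s)])
      db_t <- c(db_t, bt$dbp_mmHg[seq_len(k_d)]); db_p <- c(db_p, bp_$dbp_mmHg[seq_len(k_d)])
    }
    list(sbp = if (length(sb_t)) bp_agreement(sb_t, sb_p) else NULL,
         dbp = if (length(db_t)) bp_agreement(db_t, db_p) else NULL)
  })

  row <- data.frame(model = config$model, window_s = config$window_s,
                    step_s = config$step_s, feature_mode = config$feature_mode,
                    signal_set = config$signal_set,
                    r2 = rep$r2, mse = rep$mse, mae = rep$mae,
                    mape = rep$mape, ev = rep$ev,
                    r2_lo = rep$ci["ci_low", "r2"], r2_hi = rep$ci["ci_high", "r2"],
                    mse_lo = rep$ci["ci_low", "mse"], mse_hi = rep$ci["ci_high", "mse"],
                    config_hash = hash)
  bp_reports <- Filter(Negate(is.null), list(SBP = bp$sbp, DBP = bp$dbp))
  tables <- report_tables(row, bp_reports)
  writeLines(tables$delimited, file.path(out_dir, "metric_report.tsv"))
  writeLines(tables$text, file.path(out_dir, "report.txt"))
  if (length(bp_reports)) {
    bp_df <- do.call(rbind, lapply(names(bp_reports), function(nm) {
      b <- bp_reports[[nm]]
      data.frame(which = nm, mad = b$mad, mapd = b$mapd, md = b$md,
                 sd = b$sd, cp5 = b$cp5, config_hash = hash)
    }))
    utils::write.table(bp_df, file.path(out_dir, "bp_agreement.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  logf("done", "reports written to %s", out_dir)
  invisible(out_dir)
}
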