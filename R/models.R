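# Regression model registry: the residual CNN plus ten classical
# regressors, trained either on raw signal windows or on wavelet scattering
# features, predicting either the PAP waveform directly or its 7-band MODWT
# coefficients.

PW_MODEL_NAMES <- c("glm", "ridge", "lasso", "sgd", "svr", "knn",
                    "gaussian_process", "random_forest", "extra_trees",
                    "xgboost", "resnet")

#' Model specification
#'
#' @param name one of the eleven registered model families:
#'   `r paste(PW_MODEL_NAMES, collapse = ", ")`.
#' @param input_mode `"raw"` (flattened signal windows) or `"scattering"`
#'   (wavelet scattering features).
#' @param output_mode `"waveform"` (predict the PAP window directly) or
#'   `"modwt_coeffs"` (predict the flattened 7-band MODWT coefficients,
#'   reconstructed to a waveform at prediction time). By convention raw
#'   inputs pair with waveform output and scattering inputs with
#'   coefficient output, but any combination is allowed.
#' @param hyperparams named list of model hyperparameters (e.g. `lambda`
#'   for ridge/lasso, `k` for knn, `n_blocks`/`width` for resnet,
#'   `scattering` for a [scattering_config()], `modwt_level`).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, input_mode = c("scattering", "raw"),
                       output_mode = NULL, hyperparams = list()) {
  name <- match.arg(name, PW_MODEL_NAMES)
  input_mode <- match.arg(input_mode)
  if (is.null(output_mode)) {
    output_mode <- if (input_mode == "scattering") "modwt_coeffs" else "waveform"
  }
  output_mode <- match.arg(output_mode, c("waveform", "modwt_coeffs"))
  structure(list(name = name, input_mode = input_mode,
                 output_mode = output_mode, hyperparams = hyperparams),
            class = "model_spec")
}

# --- design matrix / target assembly ---------------------------------------

model_inputs <- function(spec, windows) {
  stopifnot(inherits(windows, "window_set"))
  if (spec$input_mode == "raw") {
    d <- dim(windows$input_windows)
    list(X = matrix(windows$input_windows, nrow = d[1], ncol = d[2] * d[3]),
         tensor = NULL,
         resnet_shape = c(d[2], d[3], 1L))  # signals x features x 1 channel
  } else {
    cfg <- spec$hyperparams$scattering %||% scattering_config()
    ft <- scattering_features(windows, cfg)
    d <- dim(ft$values)
    list(X = flatten_features(ft), tensor = ft,
         resnet_shape = c(d[2], d[3], d[4]))
  }
}

model_targets <- function(spec, windows) {
  Yw <- windows$target_windows
  if (spec$output_mode == "waveform") {
    list(Y = Yw, level = NULL)
  } else {
    level <- spec$hyperparams$modwt_level %||% 6L
    Y <- t(apply(Yw, 1, function(w) flatten_coeffs(modwt_decompose(w, level))))
    list(Y = Y, level = level)
  }
}

# resnet wants [n, n_features, planes] with planes = signals x channels
resnet_input_array <- function(inp) {
  if (is.null(inp$tensor)) {
    stop("internal: resnet array requested without tensor", call. = FALSE)
  }
  v <- inp$tensor$values  # [n, s, f, c]
  d <- dim(v)
  array(aperm(v, c(1, 3, 2, 4)), dim = c(d[1], d[3], d[2] * d[4]))
}

resnet_raw_array <- function(windows) {
  a <- windows$input_windows  # [n, s, ws]
  d <- dim(a)
  array(aperm(a, c(1, 3, 2)), dim = c(d[1], d[3], d[2]))
}

# --- per-family fit/predict backends ---------------------------------------

fit_backend <- function(spec, X, Y, config) {
  hp <- spec$hyperparams
  seed <- config$seed %||% 1L
  name <- spec$name
  if (name == "glm") {
    fit <- stats::lm.fit(cbind(1, X), Y)
    B <- fit$coefficients
    B[is.na(B)] <- 0
    list(kind = "linear", B = B)
  } else if (name == "ridge") {
    lambda <- hp$lambda %||% 1
    xm <- colMeans(X); ym <- colMeans(Y)
    Xc <- sweep(X, 2, xm)
    Yc <- sweep(Y, 2, ym)
    B <- if (ncol(Xc) > nrow(Xc)) {
      K <- tcrossprod(Xc)
      diag(K) <- diag(K) + lambda
      crossprod(Xc, solve(K, Yc))
    } else {
      G <- crossprod(Xc)
      diag(G) <- diag(G) + lambda
      solve(G, crossprod(Xc, Yc))
    }
    list(kind = "linear", B = rbind(ym - drop(crossprod(matrix(xm), B)), B))
  } else if (name == "lasso") {
    lambda <- hp$lambda %||% 0.01
    fits <- lapply(seq_len(ncol(Y)), function(j) {
      glmnet::glmnet(X, Y[, j], alpha = 1, lambda = lambda,
                     standardize = TRUE)
    })
    list(kind = "per_output", fits = fits,
         pred1 = function(f, newX) as.numeric(glmnet::predict.glmnet(f, newX)))
  } else if (name == "sgd") {
    fit_sgd_linear(X, Y, lr = config$learning_rate %||% 1e-3,
                   batch = config$batch_size %||% 32,
                   epochs = config$epochs %||% 3, seed = seed)
  } else if (name == "svr") {
    fits <- lapply(seq_len(ncol(Y)), function(j) {
      e1071::svm(X, Y[, j], type = "eps-regression",
                 kernel = hp$kernel %||% "radial", cost = hp$cost %||% 1)
    })
    list(kind = "per_output", fits = fits,
         pred1 = function(f, newX) as.numeric(stats::predict(f, newX)))
  } else if (name == "knn") {
    list(kind = "knn", X = X, Y = Y, k = hp$k %||% 5L)
  } else if (name == "gaussian_process") {
    fits <- with_seed(seed, lapply(seq_len(ncol(Y)), function(j) {
      suppressMessages(
        kernlab::gausspr(X, Y[, j], kernel = "rbfdot",
                         var = hp$noise_var %||% 0.01, scaled = FALSE)
      )
    }))
    list(kind = "per_output", fits = fits,
         pred1 = function(f, newX) as.numeric(kernlab::predict(f, newX)))
  } else if (name %in% c("random_forest", "extra_trees")) {
    nt <- hp$num_trees %||% 100L
    fits <- lapply(seq_len(ncol(Y)), function(j) {
      df <- data.frame(y = Y[, j], X)
      ranger::ranger(y ~ ., data = df, num.trees = nt,
                     splitrule = if (name == "extra_trees") "extratrees" else "variance",
                     num.random.splits = if (name == "extra_trees") 1L else 1L,
                     seed = seed + j, num.threads = 1L)
    })
    list(kind = "per_output", fits = fits,
         pred1 = function(f, newX) {
           stats::predict(f, data.frame(newX))$predictions
         })
  } else if (name == "xgboost") {
    fits <- lapply(seq_len(ncol(Y)), function(j) {
      xgboost::xgboost(X, Y[, j],
                       nrounds = hp$nrounds %||% 30L,
                       max_depth = hp$max_depth %||% 4L,
                       learning_rate = hp$eta %||% 0.3, nthreads = 1L)
    })
    list(kind = "per_output", fits = fits,
         pred1 = function(f, newX) as.numeric(stats::predict(f, newX)))
  } else {
    stop("resnet is fitted through its own backend", call. = FALSE)
  }
}

fit_sgd_linear <- function(X, Y, lr, batch, epochs, seed) {
  # seeded minibatch SGD on a standardized linear model
  xm <- colMeans(X)
  xs <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, xm), 2, xs, `/`)
  n <- nrow(Xs); p <- ncol(Xs); q <- ncol(Y)
  with_seed(seed, {
    B <- matrix(0, p, q)
    b0 <- colMeans(Y)
    losses <- numeric(epochs)
    steps <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (bi in seq_len(ceiling(n / batch))) {
        idx <- ord[((bi - 1) * batch + 1):min(bi * batch, n)]
        pred <- Xs[idx, , drop = FALSE] %*% B +
          matrix(b0, length(idx), q, byrow = TRUE)
        resid <- pred - Y[idx, , drop = FALSE]
        gB <- crossprod(Xs[idx, , drop = FALSE], resid) / length(idx)
        B <- B - lr * gB
        b0 <- b0 - lr * colMeans(resid)
        steps <- steps + 1L
      }
      pred <- Xs %*% B + matrix(b0, n, q, byrow = TRUE)
      losses[ep] <- mean((pred - Y)^2)
    }
    list(kind = "sgd", B = B, b0 = b0, xm = xm, xs = xs,
         log = data.frame(epoch = seq_len(epochs), loss = losses),
         steps = steps)
  })
}

predict_backend <- function(fit, newX) {
  if (fit$kind == "linear") {
    cbind(1, newX) %*% fit$B
  } else if (fit$kind == "sgd") {
    Xs <- sweep(sweep(newX, 2, fit$xm), 2, fit$xs, `/`)
    Xs %*% fit$B + matrix(fit$b0, nrow(newX), length(fit$b0), byrow = TRUE)
  } else if (fit$kind == "knn") {
    k <- min(fit$k, nrow(fit$X))
    # squared distances via the Gram expansion
    d2 <- outer(rowSums(newX^2), rowSums(fit$X^2), `+`) -
      2 * tcrossprod(newX, fit$X)
    t(apply(d2, 1, function(row) {
      nb <- order(row)[seq_len(k)]
      colMeans(fit$Y[nb, , drop = FALSE])
    }))
  } else if (fit$kind == "per_output") {
    out <- vapply(fit$fits, fit$pred1, numeric(nrow(newX)), newX = newX)
    matrix(out, nrow = nrow(newX))
  } else if (fit$kind == "oracle") {
    # arbitrary prediction function; used to wire reference predictors
    # (e.g. the exact MODWT coefficients) through the prediction path
    fit$fun(newX)
  } else {
    stop("unknown backend kind: ", fit$kind, call. = FALSE)
  }
}

# --- public training surface ------------------------------------------------

#' Train a regression model on a window set
#'
#' Assembles inputs (raw windows or scattering features) and targets (PAP
#' windows or their MODWT coefficients) according to the model
#' specification, fits the requested family, and logs training progress for
#' iterative families. Deterministic given `config$seed` on the
#' single-threaded reference path.
#'
#' @param spec a [model_spec()].
#' @param train_windows a `window_set` of training windows.
#' @param val_windows optional validation `window_set` (its loss is logged).
#' @param config list of learning parameters: `dropout`, `learning_rate`,
#'   `batch_size`, `epochs`, `seed`.
#' @return object of class `trained_model`.
#' @export
train <- function(spec, train_windows, val_windows = NULL,
                  config = list(seed = 1L)) {
  stopifnot(inherits(spec, "model_spec"))
  if (!inherits(train_windows, "window_set") || !length(train_windows$subject_ids)) {
    stop("empty or invalid training set", call. = FALSE)
  }
  if (!is.null(val_windows) && length(val_windows$subject_ids)) {
    overlap <- intersect(unique(train_windows$subject_ids),
                         unique(val_windows$subject_ids))
    if (length(overlap)) {
      stop("train and validation sets share patients: ",
           paste(overlap, collapse = ", "), call. = FALSE)
    }
  }
  inp <- model_inputs(spec, train_windows)
  tgt <- model_targets(spec, train_windows)
  if (spec$name == "resnet") {
    Xa <- if (spec$input_mode == "raw") resnet_raw_array(train_windows) else resnet_input_array(inp)
    net <- build_resnet(inp$resnet_shape, ncol(tgt$Y),
                        n_blocks = spec$hyperparams$n_blocks %||% 4L,
                        width = spec$hyperparams$width %||% 16L,
                        seed = config$seed %||% 1L)
    net <- train_resnet(net, Xa, tgt$Y, config)
    fit <- list(kind = "resnet", net = net)
    fit_log <- net$log
  } else {
    fit <- fit_backend(spec, inp$X, tgt$Y, config)
    fit_log <- fit$log %||% data.frame(epoch = 1L,
                                       loss = mean((predict_backend(fit, inp$X) - tgt$Y)^2))
  }
  structure(list(spec = spec, fit = fit, log = fit_log,
                 seed = config$seed %||% 1L,
                 window_samples = train_windows$window_samples,
                 window_s = train_windows$window_s,
                 signals = train_windows$signals,
                 modwt_level = tgt$level,
                 train_subjects = unique(train_windows$subject_ids)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s (%s inputs -> %s), %d-sample windows\n",
              x$spec$name, x$spec$input_mode, x$spec$output_mode,
              x$window_samples))
  invisible(x)
}

#' Predict PAP waveform windows
#'
#' Runs the trained model on new windows and always returns waveforms in
#' mmHg: coefficient-mode predictions are passed through the inverse MODWT
#' before return.
#'
#' @param model a `trained_model`.
#' @param inputs a `window_set` preprocessed identically to training.
#' @return matrix `n_windows x window_samples` of predicted PAP.
#' @export
predict_pap <- function(model, inputs) {
  stopifnot(inherits(model, "trained_model"))
  if (!inherits(inputs, "window_set")) {
    stop("`inputs` must be a window_set", call. = FALSE)
  }
  if (inputs$window_samples != model$window_samples ||
      !identical(inputs$signals, model$signals)) {
    stop("input windows do not match the model's training configuration",
         call. = FALSE)
  }
  if (model$fit$kind == "resnet") {
    Xa <- if (model$spec$input_mode == "raw") {
      resnet_raw_array(inputs)
    } else {
      resnet_input_array(model_inputs(model$spec, inputs))
    }
    Yhat <- predict_resnet(model$fit$net, Xa)
  } else {
    inp <- model_inputs(model$spec, inputs)
    Yhat <- predict_backend(model$fit, inp$X)
  }
  if (model$spec$output_mode == "modwt_coeffs") {
    ws <- model$window_samples
    lvl <- model$modwt_level
    Yhat <- t(apply(Yhat, 1, function(v) {
      modwt_reconstruct(coeffs_from_vector(v, ws, lvl))
    }))
  }
  Yhat
}

#' Grid search over learning parameters
#'
#' Trains one model per grid point and selects the configuration with the
#' highest validation R-squared; ties are broken by smallest validation MSE,
#' then by grid order.
#'
#' @param spec a [model_spec()].
#' @param grid named list of parameter vectors (expanded to their cross
#'   product), e.g. `list(learning_rate = c(1e-4, 1e-3), epochs = 1:2)`.
#' @param train_windows,val_windows disjoint-patient window sets.
#' @param config base learning configuration; grid entries override it.
#' @return list with `best_config`, `best_model`, and `scores` (one row per
#'   grid point, with validation R-squared and MSE).
#' @export
grid_search <- function(spec, grid, train_windows, val_windows,
                        config = list(seed = 1L)) {
  if (!length(grid)) stop("`grid` must be non-empty", call. = FALSE)
  tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  y_true <- as.numeric(t(val_windows$target_windows))
  scores <- data.frame(tab, r2 = NA_real_, mse = NA_real_)
  models <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cfg <- utils::modifyList(config, as.list(tab[i, , drop = FALSE]))
    sp <- spec
    hp_names <- intersect(names(cfg), c("lambda", "k", "n_blocks", "width",
                                        "num_trees", "nrounds", "cost"))
    sp$hyperparams[hp_names] <- cfg[hp_names]
    m <- train(sp, train_windows, val_windows, cfg)
    pred <- as.numeric(t(predict_pap(m, val_windows)))
    mets <- waveform_metrics(y_true, pred)
    scores$r2[i] <- mets$r2
    scores$mse[i] <- mets$mse
    models[[i]] <- m
  }
  best <- order(-scores$r2, scores$mse, seq_len(nrow(scores)))[1]
  list(best_config = as.list(tab[best, , drop = FALSE]),
       best_model = models[[best]], scores = scores)
}

#' Run the model/window/feature comparison
#'
#' Trains and evaluates every combination of model family, window size,
#' step size, feature mode and input signal set on a simulated cohort with
#' a patient-level train/validation/test split, and reports the five
#' waveform metrics per combination on the held-out test patients.
#'
#' @param cohort list of simulated subjects from [simulate_cohort()].
#' @param model_names subset of the model registry.
#' @param window_grid,step_grid window and step sizes, seconds.
#' @param feature_modes subset of `c("raw", "scattering")`.
#' @param signal_sets subset of `c("three", "five")`: three = RESP/PPG/ECG
#'   (noninvasive), five = ABP/CVP/RESP/PPG/ECG.
#' @param config learning configuration passed to [train()].
#' @param seed split/training seed.
#' @param filter apply [bandpass()] before segmentation.
#' @return data frame, one row per combination, with the five metrics and
#'   the signals actually used (provenance).
#' @export
run_comparison <- function(cohort, model_names = c("ridge", "knn"),
                           window_grid = 2, step_grid = 1,
                           feature_modes = c("scattering"),
                           signal_sets = c("three"),
                           config = list(seed = 1L), seed = 1L,
                           filter = FALSE) {
  sets <- list(three = c("RESP", "PPG", "ECG"),
               five = c("ABP", "CVP", "RESP", "PPG", "ECG"))
  ids <- vapply(cohort, function(s) s$record$subject_id, "")
  split <- split_by_patient(ids, seed = seed)
  recs <- lapply(cohort, `[[`, "record")
  if (filter) recs <- lapply(recs, bandpass)
  names(recs) <- ids
  rows <- list()
  for (w in window_grid) for (st in step_grid) {
    for (sset in signal_sets) {
      sig <- sets[[sset]]
      seg_all <- lapply(recs, segment, window_s = w, step_s = st,
                        input_signals = sig)
      pick <- function(which_ids) bind_window_sets(seg_all[which_ids])
      tr <- pick(split$train); va <- pick(split$val); te <- pick(split$test)
      stopifnot(!any(te$subject_ids %in% c(tr$subject_ids, va$subject_ids)))
      for (fm in feature_modes) for (mn in model_names) {
        ws <- round(PW_FS * w)
        out_mode <- if (fm == "scattering" && ws >= 225) "modwt_coeffs" else "waveform"
        sp <- model_spec(mn, input_mode = fm, output_mode = out_mode)
        m <- train(sp, tr, va, config)
        pred <- predict_pap(m, te)
        mets <- waveform_metrics(as.numeric(t(te$target_windows)),
                                 as.numeric(t(pred)))
        rows[[length(rows) + 1L]] <- data.frame(
          model = mn, window_s = w, step_s = st, feature_mode = fm,
          signal_set = sset, signals = paste(sig, collapse = "+"),
          n_test_windows = length(te$subject_ids),
          r2 = mets$r2, mse = mets$mse, mae = mets$mae,
          mape = mets$mape, ev = mets$ev)
      }
    }
  }
  do.call(rbind, rows)
}
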