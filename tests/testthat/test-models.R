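# small disjoint-patient window sets shared across model tests
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- simulate_cohort(6, duration_s = 10,
                                param_ranges = noiseless_ranges(), seed = 31)
      ids <- vapply(cohort, function(s) s$record$subject_id, "")
      segs <- lapply(cohort, function(s) segment(s$record, 1, 0.5))
      names(segs) <- ids
      cache <<- list(tr = bind_window_sets(segs[ids[1:4]]),
                     va = bind_window_sets(segs[ids[5]]),
                     te = bind_window_sets(segs[ids[6]]))
    }
    cache
  }
})

test_that("a linear map is learnable to near-perfect training R2 by ridge", {
  fx <- model_fixture()
  tr <- fx$tr
  # identity task: the target window is one of the input channels
  tr$target_windows <- tr$input_windows[, "PPG", ] * 10 + 2
  m <- train(model_spec("ridge", "raw", hyperparams = list(lambda = 1e-6)), tr,
             config = list(seed = 1))
  pred <- predict_pap(m, tr)
  mets <- waveform_metrics(as.numeric(t(tr$target_windows)), as.numeric(t(pred)))
  expect_gt(mets$r2, 0.999)
})

test_that("every classical family fits and predicts with the contracted shapes", {
  fx <- model_fixture()
  tr <- fx$tr; te <- fx$te
  # keep per-output families cheap: short windows already (125 samples)
  for (nm in c("glm", "ridge", "sgd", "knn")) {
    m <- train(model_spec(nm, "raw"), tr, config = list(seed = 2))
    p <- predict_pap(m, te)
    expect_equal(dim(p), c(length(te$subject_ids), te$window_samples))
    expect_true(all(is.finite(p)))
  }
})

test_that("per-output backends (svr, gp, forests, xgboost, lasso) handle multi-output targets", {
  set.seed(33)
  n <- 60; p <- 12; q <- 4
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(p * q), p, q)
  Y <- X %*% B + 0.05 * matrix(rnorm(n * q), n, q)
  for (nm in c("lasso", "svr", "gaussian_process", "random_forest",
               "extra_trees", "xgboost")) {
    sp <- model_spec(nm, "raw")
    fit <- papwave:::fit_backend(sp, X, Y, list(seed = 4))
    pr <- papwave:::predict_backend(fit, X)
    expect_equal(dim(pr), c(n, q))
    resid_var <- mean((pr - Y)^2) / mean(Y^2)
    expect_lt(resid_var, 0.9)  # each family beats a trivial zero predictor
  }
})

test_that("coefficient-mode predictions reconstruct through the inverse MODWT", {
  fx <- model_fixture()
  te <- fx$te
  # oracle predictor: emits the exact MODWT coefficients of the true target
  truth <- te$target_windows
  level <- 5L  # 125-sample windows support level 5
  sp <- model_spec("ridge", "raw", output_mode = "modwt_coeffs",
                   hyperparams = list(modwt_level = level))
  m <- train(sp, fx$tr, config = list(seed = 1))
  m$fit <- list(kind = "oracle", fun = function(newX) {
    t(apply(truth, 1, function(w) flatten_coeffs(modwt_decompose(w, level))))
  })
  pred <- predict_pap(m, te)
  expect_equal(pred, truth, tolerance = 1e-8)
  expect_equal(ncol(pred), 125)
})

test_that("training refuses shared patients between train and validation", {
  fx <- model_fixture()
  expect_error(train(model_spec("ridge", "raw"), fx$tr, fx$tr), "share patients")
  expect_error(train(model_spec("ridge", "raw"),
                     structure(list(subject_ids = character(0)),
                               class = "window_set")),
               "empty")
})

test_that("grid search scores every grid point and breaks ties deterministically", {
  fx <- model_fixture()
  gs <- grid_search(model_spec("ridge", "raw"),
                    list(lambda = c(1e-4, 1, 100)), fx$tr, fx$va,
                    config = list(seed = 1))
  expect_equal(nrow(gs$scores), 3)
  expect_equal(gs$best_config$lambda,
               gs$scores$lambda[which.max(gs$scores$r2)])
  one <- grid_search(model_spec("ridge", "raw"), list(lambda = 0.5),
                     fx$tr, fx$va, config = list(seed = 1))
  expect_equal(one$best_config$lambda, 0.5)
  # a config able to represent the target beats one that cannot
  tr2 <- fx$tr; va2 <- fx$va
  tr2$target_windows <- tr2$input_windows[, "PPG", ] * 5 + 20
  va2$target_windows <- va2$input_windows[, "PPG", ] * 5 + 20
  gs2 <- grid_search(model_spec("ridge", "raw"),
                     list(lambda = c(1e-8, 1e8)), tr2, va2,
                     config = list(seed = 1))
  expect_equal(gs2$best_config$lambda, 1e-8)
  expect_error(grid_search(model_spec("ridge"), list(), fx$tr, fx$va), "non-empty")
})

test_that("the comparison harness enumerates combinations and keeps provenance", {
  cohort <- simulate_cohort(6, duration_s = 10,
                            param_ranges = noiseless_ranges(), seed = 35)
  tab <- run_comparison(cohort, model_names = c("glm", "ridge"),
                        window_grid = c(1, 2), step_grid = 1,
                        feature_modes = "raw", signal_sets = c("three", "five"),
                        seed = 3)
  expect_equal(nrow(tab), 2 * 2 * 1 * 1 * 2)
  three <- tab[tab$signal_set == "three", ]
  expect_true(all(three$signals == "RESP+PPG+ECG"))
  expect_false(any(grepl("PAP|ABP|CVP", three$signals)))
  expect_true(all(c("r2", "mse", "mae", "mape", "ev") %in% names(tab)))
})

test_that("invasive channels coupled to PAP help the five-signal model", {
  # ABP shares PAP's latent beat state and amplitudes are fixed, so the
  # five-signal input contains a nearly affine copy of the target
  cohort <- simulate_cohort(8, duration_s = 12,
                            param_ranges = noiseless_ranges(), seed = 36)
  tab <- run_comparison(cohort, model_names = "ridge", window_grid = 1,
                        step_grid = 0.5, feature_modes = "raw",
                        signal_sets = c("three", "five"), seed = 4)
  expect_gte(tab$r2[tab$signal_set == "five"],
             tab$r2[tab$signal_set == "three"])
})
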