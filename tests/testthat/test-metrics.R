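test_that("waveform metrics match hand-computed values on toy vectors", {
  perfect <- waveform_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mape, 0)
  expect_equal(perfect$ev, 1)
  m <- waveform_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$r2, 1 - 1 / 2)          # SS_res 1, SS_tot 2
  expect_equal(m$mape, 100 * (1 / 3) / 3)
  const <- waveform_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(const$r2, 0)
  expect_error(waveform_metrics(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(waveform_metrics(1:3, 1:4), "equal length")
  expect_warning(z <- waveform_metrics(c(0, 1, 2), c(0, 1, 2.3)), "zero values")
  expect_equal(z$mape, 100 * mean(c(0, 0.3 / 2)))
})

test_that("per-beat agreement statistics match hand evaluation", {
  true_bp <- c(40, 42, 38, 41)
  same <- bp_agreement(true_bp, true_bp)
  expect_equal(same$mad, 0); expect_equal(same$md, 0)
  expect_equal(same$sd, 0); expect_equal(same$cp5, 100)
  plus2 <- bp_agreement(true_bp, true_bp + 2)
  expect_equal(plus2$md, 2); expect_equal(plus2$mad, 2)
  expect_equal(plus2$sd, 0); expect_equal(plus2$cp5, 100)
  expect_equal(plus2$mapd, 100 * mean(2 / true_bp))
  plus6 <- bp_agreement(true_bp, true_bp + 6)
  expect_equal(plus6$cp5, 0)
  expect_error(bp_agreement(1:3, 1:4), "pair")
})

test_that("explained variance never falls below R2 and metrics ignore pair order", {
  set.seed(51)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    yt <- rnorm(n, 20, 5)
    yp <- yt + rnorm(n, sample(c(-2, 0, 2), 1), 2)
    m <- waveform_metrics(yt, yp)
    expect_gte(m$ev + 1e-12, m$r2)
  }
  yt <- rnorm(50, 30, 4); yp <- yt + rnorm(50)
  perm <- sample(50)
  a <- waveform_metrics(yt, yp)
  b <- waveform_metrics(yt[perm], yp[perm])
  for (f in c("r2", "mse", "mae", "mape", "ev")) expect_equal(a[[f]], b[[f]])
})

test_that("bootstrap CIs are degenerate for perfect predictions and seeded", {
  set.seed(52)
  y <- matrix(rnorm(200, 30, 5), 20, 10)
  ci <- bootstrap_ci(y, y, "mse", n_reps = 500, seed = 3)
  expect_equal(diff(ci), 0)
  expect_equal(ci[1], 0)
  yp <- y + rnorm(200)
  c1 <- bootstrap_ci(y, yp, "mae", n_reps = 500, seed = 9)
  c2 <- bootstrap_ci(y, yp, "mae", n_reps = 500, seed = 9)
  expect_identical(c1, c2)
  expect_lt(c1[1], c1[2])
  expect_error(bootstrap_ci(y, yp, "mae", n_reps = 10), ">= 100")
  expect_error(bootstrap_ci(y[1, , drop = FALSE], yp[1, , drop = FALSE], "mse",
                            n_reps = 200),
               "resampling units")
})

test_that("bootstrap CI width shrinks with more data", {
  set.seed(53)
  yt_small <- rnorm(100, 30, 5)
  yp_small <- yt_small + rnorm(100, 0, 2)
  yt_big <- rnorm(10000, 30, 5)
  yp_big <- yt_big + rnorm(10000, 0, 2)
  w_small <- diff(bootstrap_ci(yt_small, yp_small, "mse", n_reps = 1000, seed = 1))
  w_big <- diff(bootstrap_ci(yt_big, yp_big, "mse", n_reps = 1000, seed = 1))
  expect_lt(w_big, w_small)
})

test_that("patient-level resampling is available and seeded", {
  set.seed(54)
  y <- matrix(rnorm(120, 25, 4), 12, 10)
  yp <- y + rnorm(120)
  gr <- rep(c("a", "b", "c"), each = 4)
  c1 <- bootstrap_ci(y, yp, "mse", n_reps = 300, seed = 2, unit = "patient",
                     groups = gr)
  expect_identical(c1, bootstrap_ci(y, yp, "mse", n_reps = 300, seed = 2,
                                    unit = "patient", groups = gr))
  expect_error(bootstrap_ci(y, yp, "mse", n_reps = 300, unit = "patient"),
               "groups")
})

test_that("report tables render, include CIs, and parse back", {
  rows <- data.frame(model = c("ridge", "knn", "resnet", "glm"),
                     window_s = 2, step_s = 1,
                     r2 = c(0.91, 0.84, 0.95, 0.6),
                     mse = c(11.5, 15.2, 8.1, 30),
                     mae = c(2.4, 3.0, 2.0, 5.5),
                     mape = c(0.9, 1.2, 0.8, 2.2),
                     ev = c(0.91, 0.85, 0.95, 0.62))
  bp <- list(SBP = bp_agreement(c(40, 41), c(39, 42)))
  out <- report_tables(rows, bp)
  expect_length(grep("\t", out$delimited), 5 + 2)  # 4+1 rows, 1+1 headers
  parsed <- parse_report_table(out$delimited)
  expect_equal(nrow(parsed), 4)
  expect_equal(parsed$r2, rows$r2)
  expect_equal(parsed$model, rows$model)
  # empty per-beat list produces a notice instead of a table
  none <- report_tables(rows, list())
  expect_true(any(grepl("no per-beat", none$text)))
  expect_error(report_tables(rows[0, ]), "at least one row")
})

test_that("full metric reports carry one CI per metric", {
  set.seed(55)
  y <- matrix(rnorm(300, 30, 6), 30, 10)
  yp <- y + rnorm(300)
  rep <- metric_report_ci(y, yp, n_reps = 200, seed = 1,
                          groups = rep(c("a", "b", "c"), each = 10))
  expect_equal(dim(rep$ci), c(2, 5))
  expect_true(all(rep$ci["ci_low", ] <= rep$ci["ci_high", ]))
  expect_equal(rep$n_patients, 3)
  expect_true(rep$ci["ci_low", "mse"] <= rep$mse &&
              rep$mse <= rep$ci["ci_high", "mse"])
})
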