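test_that("a 250-sample window decomposes into 7 full-length bands (1750 coefficients)", {
  set.seed(1)
  x <- rnorm(250)
  cv <- modwt_decompose(x)
  expect_equal(dim(cv$bands), c(7, 250))
  expect_length(flatten_coeffs(cv), 1750)
  expect_identical(rownames(cv$bands), c(paste0("D", 1:6), "A6"))
})

test_that("wavelet bands annihilate constants and the approximation carries them", {
  cv <- modwt_decompose(rep(3.7, 256))
  expect_lt(max(abs(cv$bands[1:6, ])), 1e-10)
  expect_equal(modwt_reconstruct(cv), rep(3.7, 256), tolerance = 1e-12)
})

test_that("decompose -> reconstruct is exact and linear", {
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(250)
    cv <- modwt_decompose(x)
    err <- sqrt(sum((modwt_reconstruct(cv) - x)^2) / sum(x^2))
    expect_lt(err, 1e-8)
  }
  x1 <- rnorm(250); x2 <- rnorm(250)
  c1 <- modwt_decompose(x1); c2 <- modwt_decompose(x2)
  mix <- c1
  mix$bands <- 2.5 * c1$bands - 1.3 * c2$bands
  expect_equal(modwt_reconstruct(mix), 2.5 * x1 - 1.3 * x2, tolerance = 1e-8)
  zero <- c1
  zero$bands[] <- 0
  expect_equal(modwt_reconstruct(zero), rep(0, 250))
})

test_that("the pyramid agrees with an independent frequency-domain implementation", {
  set.seed(3)
  for (n in c(250, 400)) {
    x <- rnorm(n)
    got <- modwt_decompose(x)$bands
    oracle <- modwt_fft_oracle(x)
    expect_equal(unname(got), oracle, tolerance = 1e-9)
  }
})

test_that("the transform preserves energy across bands", {
  set.seed(4)
  for (i in 1:100) {
    x <- rnorm(250)
    cv <- modwt_decompose(x)
    expect_equal(sum(cv$bands^2), sum(x^2), tolerance = 1e-6)
  }
})

test_that("windows too short for the requested level are rejected with guidance", {
  expect_error(modwt_decompose(rnorm(125), level = 6), "level <= ")
  expect_silent(modwt_decompose(rnorm(125), level = 5))
  expect_error(modwt_reconstruct(matrix(1, 1, 10)), "band matrix")
  bad <- modwt_decompose(rnorm(250))
  bad$bands <- bad$bands[1:5, ]
  expect_error(modwt_reconstruct(bad), "expected 7 bands")
})

test_that("coefficient vectors flatten and restore exactly", {
  set.seed(5)
  cv <- modwt_decompose(rnorm(250))
  v <- flatten_coeffs(cv)
  back <- coeffs_from_vector(v, 250)
  expect_equal(back$bands, cv$bands)
  expect_error(coeffs_from_vector(v[-1], 250), "expected 1750")
})

test_that("scattering of silence is silence and coefficients scale with the input", {
  z <- scattering_features(array(0, c(1, 1, 250)), window_s = 2)
  expect_equal(max(abs(z$values)), 0)
  sim <- quiet_record(seed = 11, duration_s = 6)
  x <- array(sim$record$channels$PPG[1:250], c(1, 1, 250))
  f1 <- scattering_features(x, window_s = 2)
  for (a in c(2, 0.5)) {
    fa <- scattering_features(x * a, window_s = 2)
    expect_lt(max(abs(fa$values - a * f1$values)) / max(abs(f1$values)), 1e-6)
  }
})

test_that("features at the invariance scale are stable under small shifts", {
  sim <- quiet_record(seed = 11, duration_s = 6)
  x <- sim$record$channels$PPG[1:250]
  shift <- 5   # 40 ms at 125 Hz
  xs <- c(x[-seq_len(shift)], x[seq_len(shift)])
  fa <- scattering_features(array(x, c(1, 1, 250)), window_s = 2)
  fb <- scattering_features(array(xs, c(1, 1, 250)), window_s = 2)
  ch1_a <- fa$values[, , , 1]
  ch1_b <- fb$values[, , , 1]
  rel <- sqrt(sum((ch1_a - ch1_b)^2) / sum(ch1_a^2))
  expect_lt(rel, (shift / 125) / 1)  # shift / invariance scale (1 s)
})

test_that("order >= 1 scattering paths are non-negative before averaging spread", {
  sim <- quiet_record(seed = 12, duration_s = 6)
  x <- array(sim$record$channels$ECG[1:250], c(1, 1, 250))
  ft <- scattering_features(x, window_s = 2)
  # path 1 is the zeroth-order (signed) low-pass; all later paths are
  # modulus-based and stay non-negative up to averaging ripple
  higher <- ft$values[1, 1, -(1:ft$n), ]
  expect_gt(min(higher), -1e-8 * max(abs(higher)))
})

test_that("feature dimensions depend on the configuration, not the content", {
  set.seed(6)
  dims <- replicate(50, {
    x <- array(rnorm(125), c(1, 1, 125))
    ft <- scattering_features(x, window_s = 1)
    c(ft$m, ft$n, dim(ft$values)[3])
  })
  expect_equal(length(unique(dims[1, ])), 1)
  expect_equal(length(unique(dims[2, ])), 1)
  expect_true(all(dims[3, ] == dims[1, 1] * dims[2, 1]))
})

test_that("an invariance scale longer than the window is rejected", {
  cfg <- scattering_config(invariance_scale_s = 3)
  expect_error(scattering_features(array(0, c(1, 1, 250)), cfg, window_s = 2),
               "invariance_scale_s")
})

test_that("feature flattening is invertible and sized as the dimension product", {
  sim <- quiet_record(seed = 13, duration_s = 8)
  s <- segment(sim$record, 1, 1)
  ft <- scattering_features(s)
  flat <- flatten_features(ft)
  d <- dim(ft$values)
  expect_equal(dim(flat), c(d[1], prod(d[-1])))
  back <- unflatten_features(flat, ft)
  expect_identical(back$values, ft$values)
})
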