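# Wavelet machinery: the invertible 7-band MODWT target representation and
# the Gabor wavelet scattering features.

# Symlet-4 decomposition filters (orthonormal, scaling filter sums to
# sqrt(2)); values match the standard published coefficients.
SYM4_DEC_LO <- c(-0.07576571478927333, -0.02963552764599851,
                 0.49761866763201545, 0.80373875180591614,
                 0.29785779560527736, -0.09921954357684722,
                 -0.01260396726203783, 0.03222310060404270)
SYM4_DEC_HI <- c(-0.03222310060404270, -0.01260396726203783,
                 0.09921954357684722, 0.29785779560527736,
                 -0.80373875180591614, 0.49761866763201545,
                 0.02963552764599851, -0.07576571478927333)

#' Maximal overlap discrete wavelet transform of a PAP window
#'
#' Undecimated (MODWT) sym4 decomposition with circular boundary handling:
#' detail bands D1..D`level` plus the approximation A`level`, each the full
#' window length, so a `level = 6` decomposition of a 250-sample window
#' carries 1750 coefficients. Circular filtering keeps the transform exactly
#' invertible ([modwt_reconstruct()]) and energy preserving.
#'
#' @param x numeric window.
#' @param level decomposition level (default 6, giving 7 bands).
#' @param wavelet only `"sym4"` is provided.
#' @return object of class `coeff_vector`: `bands` is a `(level+1) x n`
#'   matrix with rows D1..D`level`, A`level`.
#' @export
modwt_decompose <- function(x, level = 6L, wavelet = "sym4") {
  wavelet <- match.arg(wavelet, "sym4")
  level <- as.integer(level)
  if (level < 1L) stop("`level` must be >= 1", call. = FALSE)
  n <- length(x)
  support <- (length(SYM4_DEC_LO) - 1L) * 2^(level - 1L) + 1L
  if (n < support) {
    max_lvl <- max(1L, floor(log2((n - 1) / (length(SYM4_DEC_LO) - 1))) + 1L)
    stop(sprintf(paste0("window of %d samples is shorter than the level-%d ",
                        "filter support (%d); use level <= %d"),
                 n, level, support, max_lvl), call. = FALSE)
  }
  g <- SYM4_DEC_LO / sqrt(2)
  h <- SYM4_DEC_HI / sqrt(2)
  bands <- matrix(0, nrow = level + 1L, ncol = n)
  v <- x
  idx0 <- seq_len(n) - 1L
  for (j in seq_len(level)) {
    step <- 2^(j - 1L)
    w_j <- numeric(n)
    v_j <- numeric(n)
    for (l in seq_along(g)) {
      src <- v[((idx0 - step * (l - 1L)) %% n) + 1L]
      w_j <- w_j + h[l] * src
      v_j <- v_j + g[l] * src
    }
    bands[j, ] <- w_j
    v <- v_j
  }
  bands[level + 1L, ] <- v
  rownames(bands) <- c(paste0("D", seq_len(level)), paste0("A", level))
  structure(list(bands = bands, level = level, wavelet = wavelet, n = n),
            class = "coeff_vector")
}

#' Inverse MODWT
#'
#' Exact inverse of [modwt_decompose()] (adjoint pyramid with the same
#' circular filters): `modwt_reconstruct(modwt_decompose(x))` returns `x` to
#' machine precision.
#'
#' @param c a `coeff_vector` (or a `(level+1) x n` band matrix).
#' @return numeric vector of length `n`.
#' @export
modwt_reconstruct <- function(c) {
  bands <- if (inherits(c, "coeff_vector")) c$bands else c
  if (!is.matrix(bands) || nrow(bands) < 2L) {
    stop("`c` must carry a band matrix with detail rows plus one approximation row",
         call. = FALSE)
  }
  if (inherits(c, "coeff_vector") && nrow(bands) != c$level + 1L) {
    stop(sprintf("expected %d bands, got %d", c$level + 1L, nrow(bands)), call. = FALSE)
  }
  level <- nrow(bands) - 1L
  n <- ncol(bands)
  g <- SYM4_DEC_LO / sqrt(2)
  h <- SYM4_DEC_HI / sqrt(2)
  idx0 <- seq_len(n) - 1L
  v <- bands[level + 1L, ]
  for (j in rev(seq_len(level))) {
    step <- 2^(j - 1L)
    w_j <- bands[j, ]
    v_new <- numeric(n)
    for (l in seq_along(g)) {
      src <- ((idx0 + step * (l - 1L)) %% n) + 1L
      v_new <- v_new + h[l] * w_j[src] + g[l] * v[src]
    }
    v <- v_new
  }
  v
}

#' Flatten / restore a MODWT coefficient vector
#'
#' `flatten_coeffs` lays the 7 bands out row-by-row into one vector of
#' length `(level+1) * n` (the coefficient-mode regression target);
#' `coeffs_from_vector` is its exact inverse.
#'
#' @param c a `coeff_vector`.
#' @return numeric vector of length `(level+1) * n`.
#' @export
flatten_coeffs <- function(c) {
  stopifnot(inherits(c, "coeff_vector"))
  as.numeric(t(c$bands))
}

#' @rdname flatten_coeffs
#' @param v flattened coefficient vector.
#' @param n window length in samples.
#' @param level decomposition level.
#' @export
coeffs_from_vector <- function(v, n, level = 6L) {
  if (length(v) != (level + 1L) * n) {
    stop(sprintf("expected %d coefficients (%d bands x %d samples), got %d",
                 (level + 1L) * n, level + 1L, n, length(v)), call. = FALSE)
  }
  bands <- t(matrix(v, nrow = n, ncol = level + 1L))
  rownames(bands) <- c(paste0("D", seq_len(level)), paste0("A", level))
  structure(list(bands = bands, level = as.integer(level), wavelet = "sym4", n = n),
            class = "coeff_vector")
}

# ---------------------------------------------------------------------------
# Wavelet scattering transform

#' Scattering transform configuration
#'
#' Configuration of the Gabor wavelet scattering features: a two-stage
#' cascade of analytic Gabor band-pass filters (quality factors
#' `quality_factors`, modulus nonlinearity after each stage) whose outputs
#' are low-pass averaged at `n_filterbanks` dyadically spaced invariance
#' scales; each averaging scale forms one channel of the feature tensor.
#'
#' @param n_filterbanks number of resolution-scale channels (default 4).
#' @param invariance_scale_s averaging scale of the coarsest channel in
#'   seconds; defaults to half the window length.
#' @param quality_factors wavelets per octave for the first and second
#'   cascade stages (default `c(8, 1)`).
#' @param wavelet_family only `"gabor"` is provided.
#' @return object of class `scattering_config`.
#' @export
scattering_config <- function(n_filterbanks = 4L, invariance_scale_s = NULL,
                              quality_factors = c(8, 1),
                              wavelet_family = "gabor") {
  wavelet_family <- match.arg(wavelet_family, "gabor")
  if (n_filterbanks < 1L) stop("`n_filterbanks` must be >= 1", call. = FALSE)
  if (length(quality_factors) < 2L) quality_factors <- rep(quality_factors, 2L)[1:2]
  if (any(quality_factors < 1)) stop("quality factors must be >= 1", call. = FALSE)
  structure(list(n_filterbanks = as.integer(n_filterbanks),
                 invariance_scale_s = invariance_scale_s,
                 quality_factors = quality_factors[1:2],
                 wavelet_family = wavelet_family),
            class = "scattering_config")
}

# analytic Gabor filterbank in the frequency domain for an n-sample window
gabor_filterbank <- function(n, fs, q, f_min) {
  f <- (seq_len(n) - 1) * fs / n
  ratio <- 2^(-1 / q)
  centers <- c()
  xi <- fs / 2 * ratio
  while (xi >= f_min) {
    centers <- c(centers, xi)
    xi <- xi * ratio
  }
  if (!length(centers)) centers <- fs / 4
  sigma <- centers / (q * 2.3548)  # FWHM = center / Q
  psi <- vapply(seq_along(centers), function(k) {
    exp(-(f - centers[k])^2 / (2 * sigma[k]^2))
  }, numeric(n))
  list(psi = psi, centers = centers)
}

# Gaussian low-pass (frequency domain, symmetric) with time scale T seconds
gauss_lowpass <- function(n, fs, T) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sigma_f <- 1 / (pi * T)
  exp(-f^2 / (2 * sigma_f^2))
}

# Precompute all filters and the path table for a given window length.
scattering_plan <- function(ws, window_s, config) {
  T <- config$invariance_scale_s %||% (window_s / 2)
  if (T > window_s + 1e-9) {
    stop("`invariance_scale_s` must not exceed the window duration", call. = FALSE)
  }
  f_min <- max(1 / T, PW_FS / ws)
  fb1 <- gabor_filterbank(ws, PW_FS, config$quality_factors[1], f_min)
  fb2 <- gabor_filterbank(ws, PW_FS, config$quality_factors[2], f_min)
  # second-order paths: only strictly frequency-decreasing pairs carry energy
  pairs <- which(outer(fb2$centers, fb1$centers,
                       function(c2, c1) c2 < c1 / 2), arr.ind = TRUE)
  phis <- vapply(seq_len(config$n_filterbanks), function(c) {
    gauss_lowpass(ws, PW_FS, T / 2^(c - 1))
  }, numeric(ws))
  n_frames <- min(ws, max(4L, round(8 * window_s)))
  frame_idx <- unique(round(seq(1, ws, length.out = n_frames)))
  m <- 1L + ncol(fb1$psi) + nrow(pairs)
  list(T = T, fb1 = fb1, fb2 = fb2, pairs = pairs, phis = phis,
       frame_idx = frame_idx, m = m, n = length(frame_idx),
       n_channels = config$n_filterbanks)
}

# scattering coefficients of one window (one signal): matrix (m*n) x channels
scatter_one <- function(x, plan) {
  ws <- length(x)
  X <- stats::fft(x)
  # first-order moduli
  U1 <- Mod(stats::mvfft(plan$fb1$psi * X, inverse = TRUE)) / ws
  # second-order moduli
  FU1 <- stats::mvfft(U1)
  if (nrow(plan$pairs)) {
    spec2 <- plan$fb2$psi[, plan$pairs[, 1], drop = FALSE] *
      FU1[, plan$pairs[, 2], drop = FALSE]
    U2 <- Mod(stats::mvfft(spec2, inverse = TRUE)) / ws
  } else {
    U2 <- matrix(0, ws, 0)
  }
  U <- cbind(x, U1, U2)  # m columns of un-averaged path outputs
  FU <- stats::mvfft(U)
  out <- matrix(0, plan$m * plan$n, plan$n_channels)
  for (c in seq_len(plan$n_channels)) {
    S <- Re(stats::mvfft(FU * plan$phis[, c], inverse = TRUE)) / ws
    out[, c] <- as.numeric(t(S[plan$frame_idx, , drop = FALSE]))
  }
  out
}

#' Wavelet scattering features of a window set
#'
#' Computes translation-stable scattering coefficients for every input
#' signal of every window: a zeroth-order low-pass path, first-order Gabor
#' moduli, and frequency-decreasing second-order paths, each averaged at the
#' configured invariance scales and subsampled to a fixed frame grid.
#'
#' @param windows a `window_set` from [segment()] (or a plain
#'   `n x n_signals x window_samples` array plus `window_s`).
#' @param config a [scattering_config()].
#' @param window_s window duration, only needed when `windows` is an array.
#' @return object of class `feature_tensor` with `values`
#'   (`n_windows x n_signals x (m*n) x n_channels`) and layout metadata
#'   `m` (paths), `n` (frames per path).
#' @export
scattering_features <- function(windows, config = scattering_config(),
                                window_s = NULL) {
  if (inherits(windows, "window_set")) {
    arr <- windows$input_windows
    window_s <- windows$window_s
    subject_ids <- windows$subject_ids
    signals <- windows$signals
  } else {
    arr <- windows
    if (is.null(window_s)) stop("`window_s` required for array input", call. = FALSE)
    subject_ids <- NULL
    signals <- dimnames(arr)[[2]] %||% paste0("sig", seq_len(dim(arr)[2]))
  }
  stopifnot(length(dim(arr)) == 3L)
  ws <- dim(arr)[3]
  plan <- scattering_plan(ws, window_s, config)
  n_win <- dim(arr)[1]
  n_sig <- dim(arr)[2]
  values <- array(0, dim = c(n_win, n_sig, plan$m * plan$n, plan$n_channels))
  for (i in seq_len(n_win)) {
    for (s in seq_len(n_sig)) {
      values[i, s, , ] <- scatter_one(arr[i, s, ], plan)
    }
  }
  structure(list(values = values, m = plan$m, n = plan$n,
                 n_channels = plan$n_channels, signals = signals,
                 subject_ids = subject_ids, window_s = window_s,
                 config = config),
            class = "feature_tensor")
}

#' Flatten a feature tensor to one vector per window
#'
#' Lays each window's `n_signals x (m*n) x n_channels` coefficients out as a
#' long vector (signal-major, then path/frame, then channel), the input form
#' for the one-dimensional regression models. Exactly invertible via
#' [unflatten_features()].
#'
#' @param t a `feature_tensor`.
#' @return numeric matrix `n_windows x (n_signals * m * n * n_channels)`.
#' @export
flatten_features <- function(t) {
  stopifnot(inherits(t, "feature_tensor"))
  d <- dim(t$values)
  matrix(t$values, nrow = d[1], ncol = prod(d[-1]))
}

#' @rdname flatten_features
#' @param flat matrix produced by [flatten_features()].
#' @param layout the original `feature_tensor` (its metadata is reused).
#' @export
unflatten_features <- function(flat, layout) {
  stopifnot(inherits(layout, "feature_tensor"))
  d <- dim(layout$values)
  d[1] <- nrow(flat)
  out <- layout
  out$values <- array(as.numeric(flat), dim = d)
  out$subject_ids <- NULL
  out
}
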