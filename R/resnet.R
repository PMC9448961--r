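# 1-D residual convolutional network for signal-to-signal regression,
# implemented on plain matrices (im2col convolutions, explicit backward
# pass) so training is deterministic given a seed on a single thread.
#
# Layer accounting: one stem convolution + n_blocks bottleneck blocks of
# three convolutions each + one 1x1 pre-head convolution. With the default
# 16 blocks the network introspects to exactly 50 convolutional layers.
# Shortcut connections are identity adds (constant channel width), so they
# contribute no convolutions.

conv_param <- function(n_out, n_in, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  sd <- sqrt(2 / (n_in * k))  # He initialisation
  list(W = array(stats::rnorm(n_out * n_in * k, 0, sd), dim = c(n_out, n_in, k)),
       b = numeric(n_out), stride = as.integer(stride), pad = as.integer(pad),
       k = as.integer(k), n_in = as.integer(n_in), n_out = as.integer(n_out))
}

conv_wmat <- function(p) {
  # [k * n_in, n_out], kernel index fastest within each input plane
  matrix(aperm(p$W, c(3, 2, 1)), nrow = p$k * p$n_in)
}

conv_out_len <- function(L, p) (L + 2L * p$pad - p$k) %/% p$stride + 1L

# gather index for im2col on the padded axis (kernel offset fastest)
conv_gather_idx <- function(L, p) {
  Lout <- conv_out_len(L, p)
  as.vector(outer(seq_len(p$k), (seq_len(Lout) - 1L) * p$stride, `+`))
}

# forward one sample: X [L, n_in] -> list(out [Lout, n_out], cache)
conv1d_forward <- function(p, X) {
  L <- nrow(X)
  Xp <- rbind(matrix(0, p$pad, ncol(X)), X, matrix(0, p$pad, ncol(X)))
  idx <- conv_gather_idx(L, p)
  Lout <- conv_out_len(L, p)
  patches <- matrix(aperm(array(Xp[idx, , drop = FALSE],
                                dim = c(p$k, Lout, p$n_in)),
                          c(2, 1, 3)),
                    nrow = Lout)
  out <- patches %*% conv_wmat(p)
  out <- sweep(out, 2, p$b, `+`)
  list(out = out, patches = patches, idx = idx, L = L, Lpad = nrow(Xp))
}

# backward one sample: returns gradients and dX [L, n_in]
conv1d_backward <- function(p, cache, dOut) {
  Wmat <- conv_wmat(p)
  dW_mat <- t(dOut) %*% cache$patches           # [n_out, k*n_in]
  db <- colSums(dOut)
  dpatches <- dOut %*% t(Wmat)                  # [Lout, k*n_in]
  Lout <- nrow(dOut)
  dp_rows <- matrix(aperm(array(dpatches, dim = c(Lout, p$k, p$n_in)),
                          c(2, 1, 3)),
                    nrow = p$k * Lout)          # rows aligned with gather idx
  dXp <- rowsum(dp_rows, group = cache$idx, reorder = FALSE)
  ord <- as.integer(rownames(dXp))
  dXfull <- matrix(0, cache$Lpad, p$n_in)
  dXfull[ord, ] <- dXp
  dX <- dXfull[(p$pad + 1L):(p$pad + cache$L), , drop = FALSE]
  dW <- aperm(array(t(dW_mat), dim = c(p$k, p$n_in, p$n_out)), c(3, 2, 1))
  list(dW = dW, db = db, dX = dX)
}

relu <- function(x) pmax(x, 0)

#' Build a 1-D residual convolutional network
#'
#' Constructs an (untrained) residual network for regression from a
#' `n_signals x n_features x n_channels` input block to `output_dim` linear
#' output units. The network is a stem convolution (kernel 7, stride 2),
#' `n_blocks` bottleneck residual blocks (1x1 reduce, kernel-3, 1x1 expand,
#' identity shortcut), a 1x1 pre-head convolution, global average pooling,
#' dropout, and a linear output layer; the loss is mean squared error. With
#' the default `n_blocks = 16` the architecture carries exactly 50
#' convolutional layers.
#'
#' @param input_shape integer triple `(n_signals, n_features, n_channels)`.
#' @param output_dim number of output units (e.g. 1750 for the 7-band MODWT
#'   coefficients of a 250-sample window).
#' @param n_blocks number of residual blocks (default 16).
#' @param width channel width of the trunk (default 32).
#' @param seed seed for weight initialisation.
#' @return object of class `resnet_model`.
#' @export
build_resnet <- function(input_shape, output_dim, n_blocks = 16L,
                         width = 32L, seed = 1L) {
  if (length(input_shape) != 3L || any(input_shape < 1)) {
    stop("`input_shape` must be three positive integers (signals, features, channels)",
         call. = FALSE)
  }
  if (output_dim < 1) stop("`output_dim` must be positive", call. = FALSE)
  n_planes <- input_shape[1] * input_shape[3]
  bott <- max(4L, width %/% 2L)
  with_seed(seed, {
    stem <- conv_param(width, n_planes, k = 7L, stride = 2L)
    blocks <- lapply(seq_len(n_blocks), function(i) {
      list(reduce = conv_param(bott, width, k = 1L),
           conv = conv_param(bott, bott, k = 3L),
           expand = conv_param(width, bott, k = 1L))
    })
    prehead <- conv_param(width, width, k = 1L)
    head <- list(W = matrix(stats::rnorm(output_dim * width, 0, sqrt(1 / width)),
                            output_dim, width),
                 b = numeric(output_dim))
    structure(list(input_shape = as.integer(input_shape),
                   output_dim = as.integer(output_dim),
                   n_blocks = as.integer(n_blocks), width = as.integer(width),
                   stem = stem, blocks = blocks, prehead = prehead,
                   head = head, seed = as.integer(seed), trained = FALSE),
              class = "resnet_model")
  })
}

#' Introspect a residual network
#'
#' @param model a `resnet_model`.
#' @return `count_conv_layers`: the number of convolutional layers
#'   (stem + 3 per block + pre-head); `count_residual_blocks`: the number of
#'   residual blocks; `output_units`: the width of the final linear layer.
#' @export
count_conv_layers <- function(model) {
  stopifnot(inherits(model, "resnet_model"))
  1L + 3L * model$n_blocks + 1L
}

#' @rdname count_conv_layers
#' @export
count_residual_blocks <- function(model) {
  stopifnot(inherits(model, "resnet_model"))
  model$n_blocks
}

#' @rdname count_conv_layers
#' @export
output_units <- function(model) {
  stopifnot(inherits(model, "resnet_model"))
  nrow(model$head$W)
}

#' @export
print.resnet_model <- function(x, ...) {
  cat(sprintf(paste0("<resnet_model> input %s, %d residual blocks, ",
                     "%d conv layers, %d output units%s\n"),
              paste(x$input_shape, collapse = "x"), count_residual_blocks(x),
              count_conv_layers(x), output_units(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

# forward pass for one sample X [L, n_planes]; returns output vector and,
# if keep = TRUE, the caches needed for the backward pass
resnet_forward_one <- function(model, X, keep = FALSE, drop_mask = NULL) {
  caches <- if (keep) list() else NULL
  c_stem <- conv1d_forward(model$stem, X)
  a <- relu(c_stem$out)
  if (keep) caches$stem <- list(cache = c_stem, pre = c_stem$out)
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    c1 <- conv1d_forward(bl$reduce, a)
    z1 <- relu(c1$out)
    c2 <- conv1d_forward(bl$conv, z1)
    z2 <- relu(c2$out)
    c3 <- conv1d_forward(bl$expand, z2)
    pre <- a + c3$out
    if (keep) {
      caches$blocks[[i]] <- list(c1 = c1, c2 = c2, c3 = c3,
                                 p1 = c1$out, p2 = c2$out, a_in = a, pre = pre)
    }
    a <- relu(pre)
  }
  c_ph <- conv1d_forward(model$prehead, a)
  aph <- relu(c_ph$out)
  pooled <- colMeans(aph)
  if (!is.null(drop_mask)) pooled <- pooled * drop_mask
  out <- as.numeric(model$head$W %*% pooled + model$head$b)
  if (keep) {
    caches$prehead <- list(cache = c_ph, pre = c_ph$out)
    caches$pooled <- pooled
    caches$Lph <- nrow(aph)
    caches$drop_mask <- drop_mask
  }
  list(out = out, caches = caches)
}

# backward pass for one sample; returns a gradient structure mirroring the
# parameters
resnet_backward_one <- function(model, caches, dOut) {
  g <- list(blocks = vector("list", model$n_blocks))
  dW_head <- outer(dOut, caches$pooled)
  db_head <- dOut
  dpooled <- as.numeric(crossprod(model$head$W, dOut))
  if (!is.null(caches$drop_mask)) dpooled <- dpooled * caches$drop_mask
  daph <- matrix(rep(dpooled / caches$Lph, each = caches$Lph), nrow = caches$Lph)
  dpre <- daph * (caches$prehead$pre > 0)
  bb <- conv1d_backward(model$prehead, caches$prehead$cache, dpre)
  g$prehead <- bb[c("dW", "db")]
  da <- bb$dX
  for (i in rev(seq_len(model$n_blocks))) {
    cb <- caches$blocks[[i]]
    dpre <- da * (cb$pre > 0)
    # shortcut branch
    da_in <- dpre
    b3 <- conv1d_backward(model$blocks[[i]]$expand, cb$c3, dpre)
    dz2 <- b3$dX * (cb$p2 > 0)
    b2 <- conv1d_backward(model$blocks[[i]]$conv, cb$c2, dz2)
    dz1 <- b2$dX * (cb$p1 > 0)
    b1 <- conv1d_backward(model$blocks[[i]]$reduce, cb$c1, dz1)
    g$blocks[[i]] <- list(reduce = b1[c("dW", "db")], conv = b2[c("dW", "db")],
                          expand = b3[c("dW", "db")])
    da <- da_in + b1$dX
  }
  dpre <- da * (caches$stem$pre > 0)
  bs <- conv1d_backward(model$stem, caches$stem$cache, dpre)
  g$stem <- bs[c("dW", "db")]
  g$head <- list(dW = dW_head, db = db_head)
  g
}

# apply an SGD-with-momentum step in place on the parameter list
resnet_step <- function(model, grads, vel, lr, momentum = 0.9) {
  upd <- function(p, gW, gb, vW, vb) {
    vW <- momentum * vW - lr * gW
    vb <- momentum * vb - lr * gb
    p$W <- p$W + vW
    p$b <- p$b + vb
    list(p = p, vW = vW, vb = vb)
  }
  u <- upd(model$stem, grads$stem$dW, grads$stem$db, vel$stem$vW, vel$stem$vb)
  model$stem <- u$p; vel$stem <- u[c("vW", "vb")]
  for (i in seq_len(model$n_blocks)) {
    for (part in c("reduce", "conv", "expand")) {
      u <- upd(model$blocks[[i]][[part]], grads$blocks[[i]][[part]]$dW,
               grads$blocks[[i]][[part]]$db,
               vel$blocks[[i]][[part]]$vW, vel$blocks[[i]][[part]]$vb)
      model$blocks[[i]][[part]] <- u$p
      vel$blocks[[i]][[part]] <- u[c("vW", "vb")]
    }
  }
  u <- upd(model$prehead, grads$prehead$dW, grads$prehead$db,
           vel$prehead$vW, vel$prehead$vb)
  model$prehead <- u$p; vel$prehead <- u[c("vW", "vb")]
  u <- upd(model$head, grads$head$dW, grads$head$db, vel$head$vW, vel$head$vb)
  model$head <- u$p; vel$head <- u[c("vW", "vb")]
  list(model = model, vel = vel)
}

zero_velocity <- function(model) {
  z <- function(p) list(vW = p$W * 0, vb = p$b * 0)
  list(stem = z(model$stem),
       blocks = lapply(model$blocks, function(bl) lapply(bl, z)),
       prehead = z(model$prehead), head = z(model$head))
}

# accumulate two gradient structures
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  add <- function(x, y) list(dW = x$dW + y$dW, db = x$db + y$db)
  list(stem = add(a$stem, b$stem),
       blocks = lapply(seq_along(a$blocks), function(i) {
         lapply(stats::setNames(nm = c("reduce", "conv", "expand")), function(part) {
           add(a$blocks[[i]][[part]], b$blocks[[i]][[part]])
         })
       }),
       prehead = add(a$prehead, b$prehead),
       head = add(a$head, b$head))
}

grad_scale <- function(g, s) {
  sc <- function(x) list(dW = x$dW * s, db = x$db * s)
  list(stem = sc(g$stem),
       blocks = lapply(g$blocks, function(bl) lapply(bl, sc)),
       prehead = sc(g$prehead), head = sc(g$head))
}

#' Train a residual network by seeded minibatch SGD
#'
#' Mean-squared-error training with momentum SGD and inverted dropout on the
#' pooled representation. Single-threaded and fully deterministic given
#' `config$seed`.
#'
#' @param model a `resnet_model` from [build_resnet()].
#' @param X input array `n x n_features x n_planes`.
#' @param Y target matrix `n x output_dim`.
#' @param config list with `learning_rate`, `batch_size`, `epochs`,
#'   `dropout` (fraction in \[0, 0.5\]) and `seed`.
#' @return the trained model, with `$log` holding per-epoch mean training
#'   loss and the optimizer step count.
#' @export
train_resnet <- function(model, X, Y,
                         config = list(learning_rate = 1e-3, batch_size = 8,
                                       epochs = 2, dropout = 0.1, seed = 1L)) {
  stopifnot(inherits(model, "resnet_model"))
  n <- dim(X)[1]
  if (n < 1) stop("empty training set", call. = FALSE)
  lr <- config$learning_rate %||% 1e-3
  bs <- config$batch_size %||% 8
  epochs <- config$epochs %||% 2
  dropout <- config$dropout %||% 0
  with_seed(config$seed %||% 1L, {
    vel <- zero_velocity(model)
    log <- data.frame(epoch = integer(0), loss = numeric(0))
    steps <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batches <- ceiling(n / bs)
      for (bi in seq_len(n_batches)) {
        idx <- ord[((bi - 1) * bs + 1):min(bi * bs, n)]
        gacc <- NULL
        bloss <- 0
        for (s in idx) {
          mask <- if (dropout > 0) {
            (stats::runif(model$width) >= dropout) / (1 - dropout)
          } else NULL
          fw <- resnet_forward_one(model, matrix(X[s, , ], dim(X)[2], dim(X)[3]),
                                   keep = TRUE, drop_mask = mask)
          resid <- fw$out - Y[s, ]
          bloss <- bloss + mean(resid^2)
          dOut <- 2 * resid / length(resid)
          g <- resnet_backward_one(model, fw$caches, dOut)
          gacc <- grad_add(gacc, g)
        }
        gacc <- grad_scale(gacc, 1 / length(idx))
        st <- resnet_step(model, gacc, vel, lr)
        model <- st$model
        vel <- st$vel
        steps <- steps + 1L
        ep_loss <- ep_loss + bloss / length(idx)
      }
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n_batches))
    }
    model$log <- log
    model$steps <- steps
    model$trained <- TRUE
    model
  })
}

#' Predict with a residual network
#'
#' @param model a trained `resnet_model`.
#' @param X input array `n x n_features x n_planes`.
#' @return matrix `n x output_dim`.
#' @export
predict_resnet <- function(model, X) {
  stopifnot(inherits(model, "resnet_model"))
  n <- dim(X)[1]
  out <- matrix(0, n, model$output_dim)
  for (s in seq_len(n)) {
    out[s, ] <- resnet_forward_one(model, matrix(X[s, , ], dim(X)[2], dim(X)[3]))$out
  }
  out
}
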