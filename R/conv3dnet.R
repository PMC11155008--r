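# conv3DNet: a compact trainable 3D CNN
#
# Tensors are 5D arrays with dim (x, y, z, channel, batch). Convolutions
# are implemented as im2col + one BLAS matrix multiply per layer, with
# hand-derived backward passes, so the network trains on CPU with no
# external deep-learning runtime.

#' Model configuration for conv3DNet
#'
#' Defines the fixed architecture: three [conv3D -> ReLU -> 2x2x2 max
#' pool] stages, a flatten, one hidden fully-connected layer with ReLU,
#' a 2-unit output layer and a softmax. Kernels use same-padding, so each
#' pooling stage halves the side length; `input_size` must therefore be
#' divisible by `pool_size^3` (= 8).
#'
#' @param input_size Cubic input side length in voxels (default 64).
#' @param conv_channels Length-3 channel counts of the conv stages.
#' @param kernel_size Odd kernel side length (default 3).
#' @param pool_size Pooling factor per stage (fixed at 2).
#' @param hidden Width of the hidden fully-connected layer.
#' @param init_seed Seed for weight initialization.
#' @return A `model_config` list.
#' @examples
#' model_config()
#' tiny_model_config()  # desk-scale preset
#' @export
model_config <- function(input_size = 64, conv_channels = c(16, 32, 64),
                         kernel_size = 3, pool_size = 2, hidden = 128,
                         init_seed = 42) {
  input_size <- as.integer(input_size)
  conv_channels <- as.integer(conv_channels)
  stopifnot(length(conv_channels) == 3L, all(conv_channels > 0L),
            kernel_size %% 2L == 1L, kernel_size >= 1L, hidden >= 1L)
  if (pool_size != 2L) stop("`pool_size` is fixed at 2", call. = FALSE)
  if (input_size %% pool_size^3L != 0L || input_size < pool_size^3L) {
    stop("`input_size` must be a positive multiple of pool_size^3 (= 8)",
         call. = FALSE)
  }
  structure(
    list(
      input_size = input_size, conv_channels = conv_channels,
      kernel_size = as.integer(kernel_size), pool_size = 2L,
      hidden = as.integer(hidden), n_classes = 2L,
      init_seed = as.integer(init_seed)
    ),
    class = "model_config"
  )
}

#' @rdname model_config
#' @export
tiny_model_config <- function(input_size = 16, conv_channels = c(4, 8, 16),
                              hidden = 32, init_seed = 42) {
  model_config(input_size = input_size, conv_channels = conv_channels,
               hidden = hidden, init_seed = init_seed)
}

# shapes of every parameter tensor, in fixed exchange order
parameter_shapes <- function(cfg) {
  k <- cfg$kernel_size
  ch <- c(1L, cfg$conv_channels)
  side <- cfg$input_size %/% 8L
  fan_in <- side^3L * cfg$conv_channels[3L]
  shapes <- list()
  for (l in 1:3) {
    shapes[[sprintf("conv%d_W", l)]] <- c(k, k, k, ch[l], ch[l + 1L])
    shapes[[sprintf("conv%d_b", l)]] <- ch[l + 1L]
  }
  shapes$fc1_W <- c(fan_in, cfg$hidden)
  shapes$fc1_b <- cfg$hidden
  shapes$fc2_W <- c(cfg$hidden, cfg$n_classes)
  shapes$fc2_b <- cfg$n_classes
  shapes
}

#' Build a conv3DNet model
#'
#' Initializes all weights from `cfg$init_seed` (He-scaled normal for
#' weights, zeros for biases); two builds from the same config are
#' bit-identical.
#'
#' @param cfg A [model_config()].
#' @return A model handle (environment with `cfg` and `params`).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  shapes <- parameter_shapes(cfg)
  params <- with_seed(cfg$init_seed, {
    lapply(shapes, function(s) {
      if (length(s) == 1L) {
        numeric(s)
      } else {
        fan_in <- prod(s[-length(s)])
        array(stats::rnorm(prod(s), 0, sqrt(2 / fan_in)), dim = s)
      }
    })
  })
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$params <- params
  class(m) <- "conv3dnet"
  m
}

#' @export
print.conv3dnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<conv3DNet> input %d^3, channels %s, hidden %d, %d parameters\n",
    x$cfg$input_size, paste(x$cfg$conv_channels, collapse = "/"),
    x$cfg$hidden, np
  ))
  invisible(x)
}

# ---- layer primitives ------------------------------------------------------

im2col3d <- function(x, k) {
  d <- dim(x)  # (D, D, D, C, B)
  D <- d[1L]; C <- d[4L]; B <- d[5L]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(D + 2L * p, D + 2L * p, D + 2L * p, C, B))
  xp[p + seq_len(D), p + seq_len(D), p + seq_len(D), , ] <- x
  k3 <- k^3L
  M <- matrix(0, D^3L * B, k3 * C)
  o <- 0L
  for (dz in 0:(k - 1L)) for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    # column order must match matrix(W, k^3*C, Cout): x-offset fastest
    o_lin <- dx + k * dy + k * k * dz + 1L
    sl <- xp[dx + seq_len(D), dy + seq_len(D), dz + seq_len(D), , ,
             drop = FALSE]
    sl <- aperm(sl, c(1L, 2L, 3L, 5L, 4L))  # (D,D,D,B,C)
    M[, o_lin + k3 * (seq_len(C) - 1L)] <- matrix(sl, D^3L * B, C)
    o <- o + 1L
  }
  M
}

col2im3d <- function(dM, D, C, B, k) {
  p <- (k - 1L) %/% 2L
  k3 <- k^3L
  dxp <- array(0, c(D + 2L * p, D + 2L * p, D + 2L * p, C, B))
  for (dz in 0:(k - 1L)) for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    o_lin <- dx + k * dy + k * k * dz + 1L
    sl <- array(dM[, o_lin + k3 * (seq_len(C) - 1L)], c(D, D, D, B, C))
    sl <- aperm(sl, c(1L, 2L, 3L, 5L, 4L))
    idx <- list(dx + seq_len(D), dy + seq_len(D), dz + seq_len(D))
    dxp[idx[[1L]], idx[[2L]], idx[[3L]], , ] <-
      dxp[idx[[1L]], idx[[2L]], idx[[3L]], , , drop = FALSE] + sl
  }
  dxp[p + seq_len(D), p + seq_len(D), p + seq_len(D), , , drop = FALSE]
}

conv3d_forward <- function(x, W, b) {
  d <- dim(x); D <- d[1L]; B <- d[5L]
  k <- dim(W)[1L]; Cout <- dim(W)[5L]
  M <- im2col3d(x, k)
  Y <- M %*% matrix(W, ncol = Cout)
  Y <- sweep(Y, 2L, b, "+")
  y <- aperm(array(Y, c(D, D, D, B, Cout)), c(1L, 2L, 3L, 5L, 4L))
  list(y = y, cache = list(M = M, dims = d, k = k))
}

conv3d_backward <- function(dy, W, cache) {
  d <- cache$dims; D <- d[1L]; C <- d[4L]; B <- d[5L]
  Cout <- dim(W)[5L]; k <- cache$k
  dYmat <- matrix(aperm(dy, c(1L, 2L, 3L, 5L, 4L)), D^3L * B, Cout)
  dW <- array(crossprod(cache$M, dYmat), dim = dim(W))
  db <- colSums(dYmat)
  dM <- dYmat %*% t(matrix(W, ncol = Cout))
  dx <- col2im3d(dM, D, C, B, k)
  list(dx = dx, dW = dW, db = db)
}

maxpool2_forward <- function(x) {
  d <- dim(x); D <- d[1L]; Dh <- D %/% 2L
  ix <- seq(1L, D, 2L)
  m <- NULL; idx <- NULL
  kk <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    kk <- kk + 1L
    s <- x[ix + dx, ix + dy, ix + dz, , , drop = FALSE]
    if (is.null(m)) {
      m <- s
      idx <- array(1L, dim(s))
    } else {
      gt <- s > m
      m[gt] <- s[gt]
      idx[gt] <- kk
    }
  }
  list(y = m, cache = list(idx = idx, D = D, dims_out = dim(m)))
}

maxpool2_backward <- function(dy, cache) {
  D <- cache$D
  ix <- seq(1L, D, 2L)
  dims_in <- dim(dy)
  dims_in[1:3] <- D
  dx <- array(0, dims_in)
  kk <- 0L
  for (dz in 0:1) for (dy_ in 0:1) for (dx_ in 0:1) {
    kk <- kk + 1L
    sub <- array(0, cache$dims_out)
    sel <- cache$idx == kk
    sub[sel] <- dy[sel]
    dx[ix + dx_, ix + dy_, ix + dz, , ] <- sub
  }
  dx
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# full forward pass; with cache = TRUE returns everything backward needs
forward_conv3dnet <- function(model, x, cache = FALSE) {
  p <- model$params
  caches <- list()
  h <- x
  for (l in 1:3) {
    cv <- conv3d_forward(h, p[[sprintf("conv%d_W", l)]],
                         p[[sprintf("conv%d_b", l)]])
    r <- cv$y
    relu_mask <- r > 0
    r[!relu_mask] <- 0
    pl <- maxpool2_forward(r)
    if (cache) {
      caches[[l]] <- list(conv = cv$cache, relu = relu_mask, pool = pl$cache)
    }
    h <- pl$y
  }
  d <- dim(h); B <- d[5L]
  Xf <- t(matrix(h, prod(d[1:4]), B))        # (B, fan_in)
  H <- sweep(Xf %*% p$fc1_W, 2L, p$fc1_b, "+")
  relu_fc <- H > 0
  H[!relu_fc] <- 0
  Z <- sweep(H %*% p$fc2_W, 2L, p$fc2_b, "+")
  probs <- softmax_rows(Z)
  res <- list(probs = probs)
  if (cache) {
    res$cache <- list(stages = caches, Xf = Xf, H = H, relu_fc = relu_fc,
                      pooled_dim = d)
  }
  res
}

#' Predict class probabilities for a batch of patches
#'
#' Deterministic for fixed weights and independent of batching: a sample's
#' probabilities are the same whether it is scored alone or in a batch.
#'
#' @param model A [build_model()] handle.
#' @param x A 5D array (side, side, side, 1, n), a 3D array for a single
#'   patch, a [ct_patch()], or a list of them.
#' @return An n x 2 matrix; column 1 is the probability of class 0
#'   (nonresponsive), column 2 of class 1 (responsive). Rows sum to 1.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "conv3dnet"))
  x <- as_input_array(x, model$cfg$input_size)
  forward_conv3dnet(model, x, cache = FALSE)$probs
}

as_input_array <- function(x, side) {
  if (inherits(x, "ct_patch")) x <- x$data
  if (is.list(x) && !is.array(x)) {
    arrs <- lapply(x, function(p) if (inherits(p, "ct_patch")) p$data else p)
    out <- array(0, c(side, side, side, 1L, length(arrs)))
    for (i in seq_along(arrs)) out[, , , 1L, i] <- arrs[[i]]
    x <- out
  }
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 4L) x <- array(x, c(dim(x), 1L))
  if (!identical(dim(x)[1:3], rep(as.integer(side), 3L)) ||
      dim(x)[4L] != 1L) {
    stop(sprintf("input patches must be %d^3 single-channel, got %s",
                 side, paste(dim(x), collapse = "x")), call. = FALSE)
  }
  x
}

#' Cross-entropy loss and parameter gradients for one batch
#'
#' @param model A [build_model()] handle.
#' @param x 5D input array (see [predict_proba()]).
#' @param y Integer 0/1 labels, length = batch size.
#' @return List with `loss` (mean cross-entropy), `grads` (named like the
#'   parameters), `probs`.
#' @export
loss_and_grad <- function(model, x, y) {
  x <- as_input_array(x, model$cfg$input_size)
  B <- dim(x)[5L]
  stopifnot(length(y) == B, all(y %in% c(0L, 1L)))
  p <- model$params
  fw <- forward_conv3dnet(model, x, cache = TRUE)
  probs <- fw$probs
  ca <- fw$cache
  eps <- 1e-12
  picked <- probs[cbind(seq_len(B), y + 1L)]
  loss <- -mean(log(pmax(picked, eps)))

  onehot <- matrix(0, B, 2L)
  onehot[cbind(seq_len(B), y + 1L)] <- 1
  dZ <- (probs - onehot) / B
  grads <- list()
  grads$fc2_W <- crossprod(ca$H, dZ)
  grads$fc2_b <- colSums(dZ)
  dH <- dZ %*% t(p$fc2_W)
  dH[!ca$relu_fc] <- 0
  grads$fc1_W <- crossprod(ca$Xf, dH)
  grads$fc1_b <- colSums(dH)
  dXf <- dH %*% t(p$fc1_W)
  dh <- array(t(dXf), ca$pooled_dim)
  for (l in 3:1) {
    st <- ca$stages[[l]]
    dr <- maxpool2_backward(dh, st$pool)
    dr[!st$relu] <- 0
    bk <- conv3d_backward(dr, p[[sprintf("conv%d_W", l)]], st$conv)
    grads[[sprintf("conv%d_W", l)]] <- bk$dW
    grads[[sprintf("conv%d_b", l)]] <- bk$db
    dh <- bk$dx
  }
  list(loss = loss, grads = grads[names(p)], probs = probs)
}

#' Export and import model parameters
#'
#' `get_parameters()` returns the ordered, named list of weight arrays (a
#' "parameter set", the unit of federated exchange); the returned copy is
#' never mutated by later training. `set_parameters()` installs a
#' parameter set after checking names and shapes, and leaves predictions
#' bit-identical to the source model's.
#'
#' @param model A [build_model()] handle.
#' @param params A parameter set from [get_parameters()] (or
#'   [aggregate_fedavg()]).
#' @return `get_parameters()`: a named list of arrays;
#'   `set_parameters()`: the model, invisibly.
#' @export
get_parameters <- function(model) {
  stopifnot(inherits(model, "conv3dnet"))
  model$params
}

#' @rdname get_parameters
#' @export
set_parameters <- function(model, params) {
  stopifnot(inherits(model, "conv3dnet"))
  shapes <- parameter_shapes(model$cfg)
  if (!identical(names(params), names(shapes))) {
    bad <- setdiff(union(names(shapes), names(params)), names(params))
    if (!length(bad)) bad <- setdiff(names(params), names(shapes))
    if (!length(bad)) bad <- names(shapes)[names(shapes) != names(params)][1L]
    stop(sprintf("parameter name mismatch at '%s'", bad[1L]), call. = FALSE)
  }
  for (nm in names(shapes)) {
    want <- shapes[[nm]]
    got <- if (is.null(dim(params[[nm]]))) length(params[[nm]])
           else dim(params[[nm]])
    if (!identical(as.integer(got), as.integer(want))) {
      stop(sprintf("shape mismatch for '%s': expected %s, got %s", nm,
                   paste(want, collapse = "x"), paste(got, collapse = "x")),
           call. = FALSE)
    }
  }
  model$params <- params
  invisible(model)
}

#' Save / load a parameter set as a portable array archive
#'
#' Arrays are stored as little-endian doubles in a flat `.bin` file with a
#' JSON manifest of names and shapes alongside (`<path>.json`).
#'
#' @param params A parameter set.
#' @param path Path of the binary archive.
#' @return `save_parameters()`: `path`, invisibly; `load_parameters()`:
#'   the parameter set.
#' @export
save_parameters <- function(params, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  manifest <- list()
  for (nm in names(params)) {
    a <- params[[nm]]
    writeBin(as.double(a), con, size = 8L, endian = "little")
    manifest[[nm]] <- if (is.null(dim(a))) length(a) else dim(a)
  }
  jsonlite::write_json(manifest, paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_parameters
#' @export
load_parameters <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"),
                                  simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  out <- list()
  for (nm in names(manifest)) {
    s <- as.integer(manifest[[nm]])
    v <- readBin(con, "double", n = prod(s), size = 8L, endian = "little")
    out[[nm]] <- if (length(s) > 1L) array(v, s) else v
  }
  out
}
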