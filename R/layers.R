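# Layer-level forward/backward passes.
#
# A feature-map batch is a (H*W*N) x C matrix with 0-based row index
# r = h + H*(w + W*n); the depthwise and pooling kernels (src/conv_ops.cpp)
# use that layout directly, and every 1x1 stage is a BLAS matrix product.
# Each layer descriptor carries its geometry (H/W/C in and out) filled in at
# build time, so forward passes need no shape inference.

conv_out_len <- function(L, dk, stride, pad) (L + 2L * pad - dk) %/% stride + 1L

# ---- forward ---------------------------------------------------------------

layer_forward <- function(layer, params, buffers, x, N, train, keep) {
  cache <- NULL
  out <- switch(layer$type,
    dwconv = .dw_conv_forward(x, layer$H_in, layer$W_in, N, params$W,
                              layer$dk, layer$stride, layer$pad),
    gconv = {
      g <- layer$groups
      ci <- layer$C_in %/% g; co <- layer$C_out %/% g
      y <- matrix(0, nrow(x), layer$C_out)
      for (k in seq_len(g)) {
        ii <- ((k - 1L) * ci + 1L):(k * ci)
        oo <- ((k - 1L) * co + 1L):(k * co)
        y[, oo] <- x[, ii, drop = FALSE] %*% params$W[, , k]
      }
      y
    },
    pwconv = x %*% params$W,   # bias omitted: a bias directly before batch
                               # normalization is redundant
    linear = .col_add(x %*% params$W, params$b),
    bn = {
      eps <- 1e-5
      if (train) {
        mv <- .col_mean_var(x)
        mu <- mv$mean; v <- mv$var
        buffers$mean <- 0.9 * buffers$mean + 0.1 * mu
        buffers$var <- 0.9 * buffers$var + 0.1 * v
      } else {
        mu <- buffers$mean; v <- buffers$var
      }
      istd <- 1 / sqrt(v + eps)
      if (keep) cache <- list(x = x, mu = mu, istd = istd)
      # fused y = gamma * (x - mu) * istd + beta
      .col_affine(x, params$gamma * istd, params$beta - params$gamma * istd * mu)
    },
    bnrelu = {
      eps <- 1e-5
      if (train) {
        mv <- .col_mean_var(x)
        mu <- mv$mean; v <- mv$var
        buffers$mean <- 0.9 * buffers$mean + 0.1 * mu
        buffers$var <- 0.9 * buffers$var + 0.1 * v
      } else {
        mu <- buffers$mean; v <- buffers$var
      }
      istd <- 1 / sqrt(v + eps)
      if (keep) cache <- list(x = x, mu = mu, istd = istd)
      .bnrelu_forward(x, params$gamma * istd,
                      params$beta - params$gamma * istd * mu)
    },
    relu = .relu_forward(x),
    maxpool = {
      r <- .max_pool_forward(x, layer$H_in, layer$W_in, N, layer$k,
                             layer$stride, layer$pad)
      if (keep) cache <- list(argmax = r$argmax)
      r$out
    },
    gap = {
      HW <- layer$H_in * layer$W_in
      rowsum(x, rep(seq_len(N), each = HW), reorder = FALSE) / HW
    },
    softmax = {
      z <- x - apply(x, 1, max)
      e <- exp(z)
      e / rowSums(e)
    },
    stop("unknown layer type: ", layer$type))
  if (keep && layer$type %in% c("dwconv", "gconv", "pwconv", "linear"))
    cache <- list(x = x)
  if (keep && layer$type == "relu") cache <- list(out = out)
  if (keep && layer$type == "bnrelu") cache$out <- out
  list(out = out, cache = cache, buffers = buffers)
}

# ---- backward --------------------------------------------------------------

# Returns list(dx = ..., grads = list(...) or NULL).  need_dx = FALSE skips
# the input gradient (used at the first layer, where nothing consumes it).
layer_backward <- function(layer, params, cache, dy, N, need_dx = TRUE) {
  switch(layer$type,
    dwconv = list(
      dx = if (need_dx)
        .dw_conv_backward_input(dy, layer$H_in, layer$W_in, N, params$W,
                                layer$dk, layer$stride, layer$pad),
      grads = list(W = .dw_conv_backward_weight(cache$x, dy, layer$H_in,
                                                layer$W_in, N, layer$dk,
                                                layer$stride, layer$pad))),
    gconv = {
      g <- layer$groups
      ci <- layer$C_in %/% g; co <- layer$C_out %/% g
      dx <- matrix(0, nrow(dy), layer$C_in)
      dW <- array(0, dim = dim(params$W))
      for (k in seq_len(g)) {
        ii <- ((k - 1L) * ci + 1L):(k * ci)
        oo <- ((k - 1L) * co + 1L):(k * co)
        dyk <- dy[, oo, drop = FALSE]
        dx[, ii] <- dyk %*% t(params$W[, , k])
        dW[, , k] <- crossprod(cache$x[, ii, drop = FALSE], dyk)
      }
      list(dx = dx, grads = list(W = dW))
    },
    pwconv = list(dx = dy %*% t(params$W),
                  grads = list(W = crossprod(cache$x, dy))),
    linear = list(dx = dy %*% t(params$W),
                  grads = list(W = crossprod(cache$x, dy),
                               b = unname(colSums(dy)))),
    bn = {
      xhat <- .col_affine(cache$x, cache$istd, -cache$istd * cache$mu)
      r <- .bn_backward(dy, xhat, params$gamma * cache$istd)
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    bnrelu = {
      r <- .bnrelu_backward(dy, cache$out, cache$x, cache$mu, cache$istd,
                            params$gamma)
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    relu = list(dx = .relu_backward(dy, cache$out), grads = NULL),
    maxpool = list(dx = .max_pool_backward(dy, cache$argmax, layer$H_in,
                                           layer$W_in, N),
                   grads = NULL),
    gap = {
      HW <- layer$H_in * layer$W_in
      list(dx = dy[rep(seq_len(N), each = HW), , drop = FALSE] / HW,
           grads = NULL)
    },
    stop("no backward pass for layer type: ", layer$type))
}

#' Intra-state (depthwise) spatial convolution
#'
#' Applies one `dk` x `dk` filter per channel with zero padding and the given
#' stride: filter `m` sees only channel `m`, so temporal structure is learned
#' within a single lead-state image and no information crosses channels.
#'
#' @param x `H` x `W` x `C` array.
#' @param weights `dk` x `dk` x `C` array, one filter per input channel.
#' @param stride Positive integer stride.
#' @param pad Zero-padding width; default `floor(dk/2)` ("same" at stride 1).
#' @return `H'` x `W'` x `C` array.
#' @export
intra_state_conv <- function(x, weights, stride = 1L, pad = NULL) {
  d <- dim(x); dw <- dim(weights)
  if (length(dw) != 3 || dw[1] != dw[2]) stop("weights must be dk x dk x C")
  if (dw[3] != d[3]) stop("filter count must equal the channel count")
  dk <- dw[1]
  if (is.null(pad)) pad <- dk %/% 2L
  wm <- matrix(weights, dk * dk, d[3])
  xm <- matrix(x, d[1] * d[2], d[3])
  out <- .dw_conv_forward(xm, d[1], d[2], 1L, wm, dk, as.integer(stride),
                          as.integer(pad))
  Ho <- conv_out_len(d[1], dk, stride, pad)
  Wo <- conv_out_len(d[2], dk, stride, pad)
  array(out, dim = c(Ho, Wo, d[3]))
}

#' Inter-state (per-lead grouped) 1x1 convolution
#'
#' Splits the channels into `g` contiguous groups (with the lead-major
#' channel convention, group = lead) and applies an independent 1x1
#' convolution, i.e. a per-pixel matrix product, within each group.  No
#' information crosses groups.
#'
#' @param x `H` x `W` x `C_in` array with `C_in` divisible by `g`.
#' @param weights `(C_in/g)` x `(C_out/g)` x `g` array of group matrices.
#' @return `H` x `W` x `C_out` array.
#' @export
inter_state_conv <- function(x, weights) {
  d <- dim(x); dw <- dim(weights)
  if (length(dw) != 3) stop("weights must be (C_in/g) x (C_out/g) x g")
  g <- dw[3]
  if (d[3] %% g != 0 || d[3] %/% g != dw[1])
    stop("channel count must be divisible into g groups of the kernel's input size")
  xm <- matrix(x, d[1] * d[2], d[3])
  layer <- list(type = "gconv", groups = g, C_in = d[3], C_out = dw[2] * g)
  y <- layer_forward(layer, list(W = weights), NULL, xm, 1L, FALSE, FALSE)$out
  array(y, dim = c(d[1], d[2], dw[2] * g))
}
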