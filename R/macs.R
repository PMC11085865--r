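# Analytic multiply-accumulate (MAC) counting.
#
# Convention: one MAC is one multiply-add.  A convolution costs
# Hout * Wout * Dk^2 * (C_in / groups) * C_out, a linear layer in * out.
# Biases, normalization, activations and pooling are excluded.

layer_macs <- function(layer) {
  switch(layer$type,
    dwconv = layer$H_out * layer$W_out * layer$dk^2 * layer$C_out,
    gconv = layer$H_out * layer$W_out * (layer$C_in / layer$groups) * layer$C_out,
    pwconv = ,
    linear = layer$H_out * layer$W_out * layer$C_in * layer$C_out,
    0)
}

#' Count multiply-accumulate operations of a TETDiaNet
#'
#' @param x A [network_config()] or a built `"tetdianet_model"`.
#' @param seed Ignored unless `x` is a config that must be built (weights do
#'   not affect the count).
#' @return Object of class `"mac_count"`: data frame of per-layer counts
#'   plus a `total` attribute.
#' @export
count_macs <- function(x, seed = 0L) {
  model <- if (inherits(x, "network_config")) build_network(x, seed) else x
  stopifnot(inherits(model, "tetdianet_model"))
  rows <- lapply(seq_along(model$layers), function(i) {
    l <- model$layers[[i]]
    data.frame(layer = i, type = l$type,
               block = l$block %||% NA_integer_,
               out_shape = sprintf("%dx%dx%d", l$H_out, l$W_out, l$C_out),
               macs = layer_macs(l))
  })
  df <- do.call(rbind, rows)
  structure(df, total = sum(df$macs), class = c("mac_count", "data.frame"))
}

#' @export
print.mac_count <- function(x, ...) {
  df <- x[x$macs > 0, ]
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("total: %s MACs (%.1f M)\n",
              format(attr(x, "total"), big.mark = ","),
              attr(x, "total") / 1e6))
  invisible(x)
}

#' Total MACs
#'
#' @param x A `"mac_count"`.
#' @return The total multiply-accumulate count as a double.
#' @export
total_macs <- function(x) attr(x, "total")

#' Analytic MAC count of the standard ResNet18 topology
#'
#' Counts the 18-layer residual network: 7x7/2 stem with 64 channels, 3x3/2
#' max pool, four stages of two basic blocks at 64/128/256/512 channels with
#' stride-2 stage transitions and 1x1 projection shortcuts, global average
#' pooling, and a final linear layer.  Both the canonical variant
#' (3 input channels, 1000 classes) and the adapted variant used for
#' multi-state ECG tensors (36 channels, 2 classes) are parameterized.
#'
#' @param input_size Spatial input size (default 224).
#' @param in_channels Input channels (3 canonical, 36 adapted).
#' @param n_classes Output classes (1000 canonical, 2 adapted).
#' @return Object of class `"mac_count"`.
#' @export
resnet18_macs <- function(input_size = 224L, in_channels = 3L,
                          n_classes = 1000L) {
  rows <- list(); total_layers <- 0L
  add <- function(name, Hout, k, cin, cout) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = length(rows) + 1L, type = name,
      out_shape = sprintf("%dx%dx%d", Hout, Hout, cout),
      macs = Hout * Hout * k^2 * cin * cout)
  }
  H <- conv_out_len(input_size, 7L, 2L, 3L)
  add("stem_conv7x7", H, 7L, in_channels, 64L)
  H <- conv_out_len(H, 3L, 2L, 1L)                      # max pool
  widths <- c(64L, 128L, 256L, 512L)
  cin <- 64L
  for (s in seq_along(widths)) {
    w <- widths[s]
    stride <- if (s == 1L) 1L else 2L
    Hs <- (H + stride - 1L) %/% stride
    add(sprintf("stage%d_block1_conv1", s), Hs, 3L, cin, w)
    add(sprintf("stage%d_block1_conv2", s), Hs, 3L, w, w)
    if (stride == 2L)
      add(sprintf("stage%d_projection", s), Hs, 1L, cin, w)
    add(sprintf("stage%d_block2_conv1", s), Hs, 3L, w, w)
    add(sprintf("stage%d_block2_conv2", s), Hs, 3L, w, w)
    cin <- w; H <- Hs
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = length(rows) + 1L, type = "fc",
    out_shape = sprintf("1x1x%d", n_classes), macs = 512 * n_classes)
  df <- do.call(rbind, rows)
  structure(df, total = sum(df$macs), class = c("mac_count", "data.frame"))
}

#' Percentage MAC reduction of TETDiaNet versus ResNet18
#'
#' Computes `100 * (1 - MAC_TETDiaNet / MAC_ResNet18)` under the package's
#' counting convention.
#'
#' @param cfg A [network_config()] (default: the published architecture at
#'   224 x 224 x 36).
#' @param variant `"canonical"` compares against ResNet18 at 3 channels /
#'   1000 classes; `"adapted"` against a 36-channel, 2-class ResNet18 at the
#'   same input size.
#' @return List with `tetdianet`, `resnet18` (total MACs) and
#'   `reduction_pct`.
#' @export
mac_reduction <- function(cfg = network_config(),
                          variant = c("canonical", "adapted")) {
  variant <- match.arg(variant)
  tet <- total_macs(count_macs(cfg))
  res <- if (variant == "canonical")
    total_macs(resnet18_macs(cfg$input_size, 3L, 1000L))
  else
    total_macs(resnet18_macs(cfg$input_size, cfg$in_channels, cfg$n_classes))
  list(tetdianet = tet, resnet18 = res,
       reduction_pct = 100 * (1 - tet / res))
}
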