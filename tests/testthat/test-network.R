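test_that("intra-state convolution with a delta kernel is the identity", {
  set.seed(10)
  x <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4))
  w <- array(0, dim = c(3, 3, 4)); w[2, 2, ] <- 1
  expect_equal(intra_state_conv(x, w, stride = 1), x)
})

test_that("intra-state convolution matches the direct loop evaluation", {
  set.seed(11)
  for (rep in 1:50) {
    H <- sample(3:7, 1); W <- sample(3:7, 1); C <- sample(1:4, 1)
    dk <- sample(c(1, 3, 5), 1); stride <- sample(1:2, 1)
    x <- array(round(rnorm(H * W * C), 2), dim = c(H, W, C))
    w <- array(round(rnorm(dk * dk * C), 2), dim = c(dk, dk, C))
    got <- intra_state_conv(x, w, stride = stride)
    want <- dw_conv_oracle(x, w, stride = stride)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("intra-state output channels depend only on their own input channel", {
  set.seed(12)
  x <- array(rnorm(5 * 5 * 3), dim = c(5, 5, 3))
  w <- array(rnorm(9 * 3), dim = c(3, 3, 3))
  base <- intra_state_conv(x, w)
  x2 <- x; x2[, , 2] <- x2[, , 2] + rnorm(25)
  pert <- intra_state_conv(x2, w)
  expect_identical(base[, , 1], pert[, , 1])
  expect_identical(base[, , 3], pert[, , 3])
  expect_false(identical(base[, , 2], pert[, , 2]))
  expect_error(intra_state_conv(x, w[, , 1:2, drop = FALSE]), "filter count")
})

test_that("inter-state convolution with identity group matrices is the identity", {
  set.seed(13)
  x <- array(rnorm(4 * 4 * 6), dim = c(4, 4, 6))
  w <- array(0, dim = c(2, 2, 3)); for (g in 1:3) w[, , g] <- diag(2)
  expect_equal(inter_state_conv(x, w), x)
})

test_that("inter-state convolution matches the per-pixel matrix product oracle", {
  set.seed(14)
  for (rep in 1:50) {
    H <- sample(2:5, 1); W <- sample(2:5, 1)
    g <- sample(2:4, 1); ci <- sample(1:3, 1); co <- sample(1:3, 1)
    x <- array(sample(-5:5, H * W * g * ci, TRUE), dim = c(H, W, g * ci))
    w <- array(sample(-5:5, ci * co * g, TRUE), dim = c(ci, co, g))
    expect_equal(inter_state_conv(x, w), gconv_oracle(x, w), tolerance = 1e-6)
  }
})

test_that("inter-state groups are independent (block-diagonal Jacobian)", {
  set.seed(15)
  x <- array(rnorm(3 * 3 * 6), dim = c(3, 3, 6))
  w <- array(rnorm(2 * 2 * 3), dim = c(2, 2, 3))
  base <- inter_state_conv(x, w)
  x2 <- x; x2[, , 3] <- x2[, , 3] + rnorm(9)   # channel 3 belongs to group 2
  pert <- inter_state_conv(x2, w)
  expect_identical(base[, , 1:2], pert[, , 1:2])    # group 1 untouched
  expect_identical(base[, , 5:6], pert[, , 5:6])    # group 3 untouched
  expect_false(identical(base[, , 3:4], pert[, , 3:4]))
  expect_error(inter_state_conv(x, array(0, c(4, 4, 4))), "divisible")
})

test_that("grouped 1x1 with g = 1 equals dense linear mixing", {
  set.seed(16)
  x <- array(rnorm(4 * 4 * 5), dim = c(4, 4, 5))
  W <- matrix(rnorm(5 * 3), 5, 3)
  got <- inter_state_conv(x, array(W, dim = c(5, 3, 1)))
  want <- array(matrix(x, 16, 5) %*% W, dim = c(4, 4, 3))
  expect_equal(got, want)
})

test_that("the default network reproduces the published shape schedule", {
  m <- build_network(network_config(), seed = 0)
  expect_equal(max(vapply(m$layers, function(l) l$block %||% 0L, integer(1))), 13)
  dws <- Filter(function(l) l$type == "dwconv", m$layers)
  # per-block input sizes 224 / 56 / 56 / 56 / 28 / 28 / 14 / 14 / 14 / 14 / 7 / 7 / 7
  expect_equal(vapply(dws, `[[`, integer(1), "H_in"),
               c(224L, 56L, 56L, 56L, 28L, 28L, 14L, 14L, 14L, 14L, 7L, 7L, 7L))
  expect_equal(vapply(dws, `[[`, integer(1), "C_in"),
               c(36L, 72L, 72L, 72L, 144L, 144L, 288L, 288L, 288L, 288L,
                 576L, 576L, 576L))
  gap <- m$layers[[which(vapply(m$layers, function(l) l$type == "gap",
                                logical(1)))]]
  expect_equal(c(gap$H_in, gap$W_in, gap$C_in), c(7, 7, 576))
  last_linear <- Filter(function(l) l$type == "linear", m$layers)
  expect_equal(vapply(last_linear, `[[`, integer(1), "C_out"), c(128L, 2L))
  # halved input: pre-pool map is 4 x 4 x 576 under the floor/stride rule
  m2 <- build_network(network_config(input_size = 112), seed = 0)
  gap2 <- m2$layers[[which(vapply(m2$layers, function(l) l$type == "gap",
                                  logical(1)))]]
  expect_equal(c(gap2$H_in, gap2$W_in, gap2$C_in), c(4, 4, 576))
  expect_error(network_config(groups = 5), "not divisible")
})

test_that("a TETDia block composes its three stages with the expected shapes", {
  set.seed(17)
  x <- array(runif(20 * 20 * 36), dim = c(20, 20, 36))
  out <- tetdia_block(x, tetdia_block_config(36, 72, dk = 7, stride = 2))
  expect_equal(dim(out), c(10, 10, 72))
  out2 <- tetdia_block(array(runif(8 * 8 * 72), c(8, 8, 72)),
                       tetdia_block_config(72, 72, dk = 3, stride = 1))
  expect_equal(dim(out2), c(8, 8, 72))
  # zero input through inference-mode normalization stays exactly zero
  z <- tetdia_block(array(0, dim = c(8, 8, 72)),
                    tetdia_block_config(72, 144), train = FALSE)
  expect_true(all(z == 0))
  expect_error(tetdia_block(x, tetdia_block_config(72, 72)), "channels")
})

test_that("forward pass yields normalized probabilities and the 0.5 rule", {
  cfg <- network_config(input_size = 32)
  m <- build_network(cfg, seed = 1)
  set.seed(2)
  x <- matrix(runif(32 * 32 * 36), 32 * 32, 36)
  pred <- network_predict(m, list(x))
  expect_equal(pred$p_nonCAD + pred$p_CAD, 1, tolerance = 1e-6)
  # zero final-layer weights: uniform logits, probability exactly 0.5,
  # and the tie goes to CAD ("greater than or equal to 0.5")
  li <- length(m$layers) - 1L
  m$params[[li]]$W[] <- 0; m$params[[li]]$b[] <- 0
  pred0 <- network_predict(m, list(x))
  expect_equal(pred0$p_CAD, 0.5)
  expect_equal(pred0$label, "CAD")
  expect_error(network_predict(m, list(matrix(0, 10, 36))), "input size")
})

test_that("cross-entropy reproduces its closed forms", {
  perfect <- rbind(c(1, 0), c(0, 1))
  labs <- c("non-CAD", "CAD")
  expect_equal(cross_entropy(perfect, labs), 0)
  uniform <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy(uniform, c("CAD", "CAD", "non-CAD", "non-CAD")),
               log(2))
  p <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(cross_entropy(p, c("non-CAD", "CAD")),
               -(log(0.9) + log(0.8)) / 2)
  expect_error(cross_entropy(matrix(numeric(0), 0, 2), character(0)), "empty")
  expect_error(cross_entropy(uniform, c("CAD", "CAD", "maybe", "non-CAD")),
               "maybe")
})

test_that("backpropagated gradients match finite differences through one block", {
  # 6-channel toy: one TETDia block (g = 3) + pooling head + classifier
  cfg <- list(input_size = 8L, in_channels = 6L)
  net <- list(layers = list(), input_size = 8L, in_channels = 6L)
  net <- tetdia:::add_layer(net, list(type = "dwconv", dk = 3L, stride = 1L,
                                      pad = 1L))
  net <- tetdia:::add_layer(net, list(type = "bnrelu"))
  net <- tetdia:::add_layer(net, list(type = "gconv", groups = 3L, C_out = 6L))
  net <- tetdia:::add_layer(net, list(type = "bnrelu"))
  net <- tetdia:::add_layer(net, list(type = "pwconv", C_out = 6L))
  net <- tetdia:::add_layer(net, list(type = "bnrelu"))
  net <- tetdia:::add_layer(net, list(type = "gap"))
  net <- tetdia:::add_layer(net, list(type = "linear", C_out = 2L))
  net <- tetdia:::add_layer(net, list(type = "softmax"))
  set.seed(20)
  model <- structure(list(cfg = cfg, layers = net$layers,
                          params = lapply(net$layers, tetdia:::init_layer_params),
                          buffers = lapply(net$layers, function(l)
                            if (l$type == "bnrelu")
                              list(mean = numeric(l$C_in), var = rep(1, l$C_in))),
                          seed = 20L), class = "tetdianet_model")
  n <- 3
  x <- matrix(runif(8 * 8 * n * 6), 8 * 8 * n, 6)
  y <- tetdia:::label_onehot(c("CAD", "non-CAD", "CAD"))
  fw <- tetdia:::net_forward(model, x, n, train = TRUE, keep_cache = TRUE)
  gr <- tetdia:::net_backward(model, fw$caches, (fw$probs - y) / n, n)
  loss_of <- function(mod) {
    p <- tetdia:::net_forward(mod, x, n, train = TRUE)$probs
    cross_entropy(p, y)
  }
  eps <- 1e-6
  set.seed(21)
  for (li in c(1, 2, 3, 5, 8)) {
    for (nm in names(model$params[[li]])) {
      k <- sample(length(model$params[[li]][[nm]]), 1)
      up <- model; up$params[[li]][[nm]][k] <- up$params[[li]][[nm]][k] + eps
      dn <- model; dn$params[[li]][[nm]][k] <- dn$params[[li]][[nm]][k] - eps
      fd <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      an <- unname(gr[[li]][[nm]][k])
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("MAC counts follow the stated convention layer by layer", {
  mc <- count_macs(network_config())
  df <- as.data.frame(mc)
  dw1 <- df$macs[df$type == "dwconv"][1]
  expect_equal(dw1, 112 * 112 * 49 * 36)            # 7x7 depthwise, stride 2
  pw1 <- df$macs[df$type == "pwconv"][1]
  expect_equal(pw1, 112 * 112 * 36 * 72)            # dense 1x1 mixing
  g1 <- df$macs[df$type == "gconv"][1]
  expect_equal(g1, 112 * 112 * 3 * 36)              # grouped 1x1, C/g = 3
  dw2 <- df$macs[df$type == "dwconv"][2]
  expect_equal(dw2, 56 * 56 * 9 * 72)               # 3x3 depthwise stride 1
  expect_equal(df$macs[df$type == "linear"], c(576 * 128, 128 * 2))
  expect_equal(total_macs(mc), sum(df$macs))
  expect_true(all(df$macs[df$type %in% c("bnrelu", "maxpool", "gap",
                                         "softmax")] == 0))
})

test_that("a toy two-block configuration totals its hand-computed MAC count", {
  cfg <- network_config(input_size = 16)
  m <- build_network(cfg, seed = 0)
  keep <- vapply(m$layers, function(l) (l$block %||% 99L) <= 2L, logical(1))
  m$layers <- m$layers[keep]
  df <- as.data.frame(count_macs(m))
  # block 1 at 16x16x36: dw 8x8x49x36, g 8x8x3x36, pw 8x8x36x72 (stride 2)
  # block 2 at 4x4x72 (after 3x3/2 pool): dw 4x4x9x72, g 4x4x6x72, pw 4x4x72x72
  hand <- 8^2 * 49 * 36 + 8^2 * 3 * 36 + 8^2 * 36 * 72 +
    4^2 * 9 * 72 + 4^2 * 6 * 72 + 4^2 * 72 * 72
  expect_equal(sum(df$macs), hand)
})

test_that("the analytic ResNet18 count matches its closed forms", {
  canon <- resnet18_macs()
  df <- as.data.frame(canon)
  expect_equal(df$macs[1], 112 * 112 * 49 * 3 * 64)       # stem
  two_cls <- resnet18_macs(n_classes = 2)
  expect_equal(total_macs(canon) - total_macs(two_cls), 512 * 998)
  adapted <- resnet18_macs(in_channels = 36)
  expect_equal(as.data.frame(adapted)$macs[1], df$macs[1] * 36 / 3)
  expect_equal(total_macs(adapted) - total_macs(canon),
               df$macs[1] * (36 / 3 - 1))
})
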