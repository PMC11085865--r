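#' Otsu's threshold of a grayscale image
#'
#' Maximizes the between-class variance over the 256 candidate cuts of an
#' 8-bit histogram; the smallest maximizing threshold is returned.
#'
#' @param image Matrix with values 0--255.
#' @return Integer threshold `t` in 0--255 (foreground: values `<= t` under
#'   the package's dark-trace polarity).
#' @export
otsu_threshold <- function(image) {
  v <- as.integer(round(as.numeric(image)))
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  p <- h / n
  omega <- cumsum(p)                       # P(class0) for thresholds 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L
}

# Separable Gaussian blur with edge-renormalized kernels (a uniform image is
# unchanged, including at the borders).
gaussian_blur <- function(image, sigma = 1, radius = 3L) {
  k <- exp(-0.5 * ((-radius):radius / sigma)^2)
  smooth_1d <- function(m) {
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m)); wt <- numeric(n)
    for (o in (-radius):radius) {
      src <- (1:n) + o
      ok <- src >= 1 & src <= n
      w <- k[o + radius + 1L]
      acc[ok, ] <- acc[ok, ] + w * m[src[ok], , drop = FALSE]
      wt[ok] <- wt[ok] + w
    }
    acc / wt
  }
  t(smooth_1d(t(smooth_1d(image))))
}

# Local-mean (adaptive) threshold: pixel is trace if below its window mean
# minus `offset`.  Window means come from an edge-clamped integral image.
adaptive_binarize <- function(image, window = 31L, offset = 10) {
  H <- nrow(image); W <- ncol(image)
  r <- window %/% 2L
  M <- t(apply(apply(image, 2, cumsum), 1, cumsum))  # M[i,j] = sum image[1:i,1:j]
  S <- rbind(0, cbind(0, M))
  i0 <- pmax(1:H - r, 1L); i1 <- pmin(1:H + r, H)
  j0 <- pmax(1:W - r, 1L); j1 <- pmin(1:W + r, W)
  area <- outer(i1 - i0 + 1L, j1 - j0 + 1L)
  m <- (S[i1 + 1L, j1 + 1L, drop = FALSE] - S[i0, j1 + 1L, drop = FALSE] -
          S[i1 + 1L, j0, drop = FALSE] + S[i0, j0, drop = FALSE]) / area
  out <- matrix(255, H, W)
  out[image <= m - offset] <- 0
  out
}

#' Augment an ECG image
#'
#' The four augmentation modes used during training: slight Gaussian
#' blurring, binarization at a seed-jittered simple threshold, Otsu
#' thresholding, and adaptive (local-mean) thresholding.  Deterministic for
#' a given `(image, mode, seed)` triple.
#'
#' @param image Grayscale matrix, values 0--255.
#' @param mode One of `"blur"`, `"simple_threshold"`, `"otsu"`, `"adaptive"`.
#' @param seed Integer seed (only `simple_threshold` draws randomness).
#' @param window,offset Adaptive-threshold window size and offset.
#' @return Augmented image, values 0--255.
#' @export
augment <- function(image, mode, seed = 0L, window = 31L, offset = 10) {
  if (length(mode) != 1 ||
      !mode %in% c("blur", "simple_threshold", "otsu", "adaptive"))
    stop("unknown augmentation mode: ", paste(mode, collapse = ", "))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  switch(mode,
    blur = gaussian_blur(image),
    simple_threshold = binarize(image,
      binarization_spec(threshold = round(runif(1, 98, 158)))),
    otsu = binarize(image, binarization_spec(threshold = otsu_threshold(image))),
    adaptive = adaptive_binarize(image, window, offset))
}
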