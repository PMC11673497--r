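#' @useDynLib medsr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- array plumbing ---------------------------------------------------------

#' Coerce an image or feature map to the internal 4-d layout
#'
#' Internally every tensor is a numeric array of dim `(H, W, C, B)`.
#' A matrix is treated as a single-channel single-image map; a 3-d array
#' as a single-image `H x W x C` map.
#'
#' @param x matrix or 3-d/4-d numeric array.
#' @return 4-d array.
#' @keywords internal
as_map4 <- function(x) {
  if (is.matrix(x)) {
    dim(x) <- c(dim(x), 1L, 1L)
  } else if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
  } else if (length(dim(x)) != 4L) {
    stop("expected a matrix or a 3-d/4-d array", call. = FALSE)
  }
  x
}

# ---- convolution / pooling wrappers ----------------------------------------

conv_fwd <- function(x, w, b, stride = 1L, pad = (dim(w)[1] - 1L) %/% 2L) {
  conv2d_fwd_cpp(x, w, b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, w, gy, stride = 1L, pad = (dim(w)[1] - 1L) %/% 2L) {
  conv2d_bwd_cpp(x, w, gy, as.integer(stride), as.integer(pad))
}

# Pool sizes are clamped to the spatial extent so that tiny maps (as arise
# inside the attention gate on small patches) still produce >= 1 output.
pool_fwd <- function(x, kernel, stride, pad = 0L) {
  d <- dim(x)
  kh <- min(kernel, d[1] + 2L * pad)
  kw <- min(kernel, d[2] + 2L * pad)
  maxpool_fwd_cpp(x, as.integer(kh), as.integer(kw),
                  as.integer(stride), as.integer(pad))
}

pool_bwd <- function(argmax, gy, H, W) {
  maxpool_bwd_cpp(argmax, gy, as.integer(H), as.integer(W))
}

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(x, gy) {
  gy * (x > 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- batch normalisation ----------------------------------------------------

# Per-channel statistics over (H, W, B); biased variance is used both for
# normalisation and for the running estimate.
bn_fwd <- function(x, gamma, beta, rmean, rvar, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xp) <- c(d[1] * d[2] * d[4], C)
  if (training) {
    mu <- colMeans(xp)
    xc <- sweep(xp, 2L, mu, "-")
    v <- colMeans(xc * xc)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
    xc <- sweep(xp, 2L, mu, "-")
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  yp <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  dim(yp) <- c(d[1], d[2], d[4], C)
  y <- aperm(yp, c(1L, 2L, 4L, 3L))
  list(y = y, xhat = xhat, inv = inv, rmean = rmean, rvar = rvar,
       training = training)
}

bn_bwd <- function(cache, gamma, gy) {
  d <- dim(gy)
  C <- d[3]
  gp <- aperm(gy, c(1L, 2L, 4L, 3L))
  dim(gp) <- c(d[1] * d[2] * d[4], C)
  xhat <- cache$xhat
  ggamma <- colSums(gp * xhat)
  gbeta <- colSums(gp)
  gxhat <- sweep(gp, 2L, gamma, "*")
  if (cache$training) {
    n <- nrow(gp)
    gxc <- sweep(
      gxhat - matrix(colMeans(gxhat), n, C, byrow = TRUE) -
        xhat * matrix(colMeans(gxhat * xhat), n, C, byrow = TRUE),
      2L, cache$inv, "*")
  } else {
    gxc <- sweep(gxhat, 2L, cache$inv, "*")
  }
  dim(gxc) <- c(d[1], d[2], d[4], C)
  gx <- aperm(gxc, c(1L, 2L, 4L, 3L))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# ---- pixel shuffle ----------------------------------------------------------

# Rearranges (H, W, r^2 * m, B) into (rH, rW, m, B). Input channel
# c = dw + r*dh + r^2*o (0-based) lands at output (r*h + dh, r*w + dw, o).
pixel_shuffle <- function(x, r) {
  d <- dim(x)
  m <- d[3] %/% (r * r)
  stopifnot(d[3] == m * r * r)
  dim(x) <- c(d[1], d[2], r, r, m, d[4])
  y <- aperm(x, c(4L, 1L, 3L, 2L, 5L, 6L))
  dim(y) <- c(r * d[1], r * d[2], m, d[4])
  y
}

pixel_unshuffle <- function(y, r) {
  d <- dim(y)
  H <- d[1] %/% r
  W <- d[2] %/% r
  dim(y) <- c(r, H, r, W, d[3], d[4])
  x <- aperm(y, c(2L, 4L, 3L, 1L, 5L, 6L))
  dim(x) <- c(H, W, r * r * d[3], d[4])
  x
}

# ---- resampling as explicit weight matrices ---------------------------------

# Keys cubic kernel, a = -1/2 (the standard bicubic interpolation kernel).
cubic_kernel <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

linear_kernel <- function(t) {
  t <- abs(t)
  ifelse(t < 1, 1 - t, 0)
}

#' 1-d resampling weight matrix
#'
#' Builds the dense `n_out x n_in` matrix `W` such that `W %*% signal`
#' resamples a length-`n_in` signal to `n_out` samples under a
#' half-pixel-centred coordinate mapping (`src = (i + 0.5) * n_in / n_out
#' - 0.5`). When downscaling, the kernel support is widened by the scale
#' factor (anti-aliasing, the `imresize` convention). Edges are handled by
#' clamping sample indices (replicate padding); each row is normalised to
#' sum to one, so constants are reproduced exactly.
#'
#' @param n_in,n_out input/output lengths.
#' @param kernel `"cubic"` or `"linear"`.
#' @param antialias widen the kernel when minifying.
#' @return `n_out x n_in` weight matrix.
#' @keywords internal
resample_matrix <- function(n_in, n_out, kernel = c("cubic", "linear"),
                            antialias = TRUE) {
  kernel <- match.arg(kernel)
  kf <- if (kernel == "cubic") cubic_kernel else linear_kernel
  support <- if (kernel == "cubic") 2 else 1
  s <- n_in / n_out
  ks <- if (antialias && s > 1) s else 1
  rad <- ceiling(support * ks) + 1L
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * s - 0.5 # 0-based source coordinate
    base <- floor(src)
    idx <- (base - rad + 1L):(base + rad)
    w <- kf((src - idx) / ks)
    keep <- w != 0
    if (!any(keep)) { # degenerate (n_in == 1): fall back to nearest
      idx <- round(src); w <- 1; keep <- TRUE
    }
    idx <- pmin(pmax(idx[keep], 0L), n_in - 1L)
    w <- w[keep]
    w <- w / sum(w)
    for (j in seq_along(idx)) W[i, idx[j] + 1L] <- W[i, idx[j] + 1L] + w[j]
  }
  W
}

#' Resample a 2-d image with a separable kernel
#'
#' @param img numeric matrix.
#' @param h_out,w_out target size.
#' @param kernel `"cubic"` (default) or `"linear"`.
#' @param antialias anti-alias when minifying (default `TRUE`).
#' @return resampled matrix.
#' @keywords internal
resize2d <- function(img, h_out, w_out, kernel = "cubic", antialias = TRUE) {
  Wr <- resample_matrix(nrow(img), h_out, kernel, antialias)
  Wc <- resample_matrix(ncol(img), w_out, kernel, antialias)
  Wr %*% img %*% t(Wc)
}

# Bilinear up/down-sampling of a 4-d map with cached weight matrices so the
# exact adjoint is available for backpropagation.
bilinear_fwd <- function(x, h_out, w_out) {
  d <- dim(x)
  Wr <- resample_matrix(d[1], h_out, "linear", antialias = FALSE)
  Wc <- resample_matrix(d[2], w_out, "linear", antialias = FALSE)
  y <- array(0, c(h_out, w_out, d[3], d[4]))
  for (b in seq_len(d[4])) for (ch in seq_len(d[3]))
    y[, , ch, b] <- Wr %*% x[, , ch, b] %*% t(Wc)
  list(y = y, Wr = Wr, Wc = Wc, d_in = d)
}

bilinear_bwd <- function(cache, gy) {
  d <- cache$d_in
  gx <- array(0, d)
  for (b in seq_len(d[4])) for (ch in seq_len(d[3]))
    gx[, , ch, b] <- t(cache$Wr) %*% gy[, , ch, b] %*% cache$Wc
  gx
}

# ---- Gaussian blur ----------------------------------------------------------

gauss_taps <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

blur_matrix <- function(n, sigma) {
  w <- gauss_taps(sigma)
  r <- (length(w) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax((i - r):(i + r), 1L), n) # replicate boundary
    for (j in seq_along(idx)) B[i, idx[j]] <- B[i, idx[j]] + w[j]
  }
  B
}

#' Gaussian blur of a 2-d image
#'
#' Separable Gaussian filter with replicate boundary handling; kernel
#' radius `ceiling(3.5 * sigma)`.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `0` returns the input.
#' @return blurred matrix.
#' @export
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Bh <- blur_matrix(nrow(img), sigma)
  Bw <- blur_matrix(ncol(img), sigma)
  Bh %*% img %*% t(Bw)
}
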