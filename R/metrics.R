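#' Mean squared error between two images
#'
#' @param x,y numeric arrays of identical shape.
#' @return mean of squared differences.
#' @export
mse <- function(x, y) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("images must have identical shape", call. = FALSE)
  mean((as.numeric(x) - as.numeric(y))^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_i^2 / MSE(x, y))` in decibels. Identical images return
#' `Inf`.
#'
#' @param x,y images of identical shape.
#' @param max_i maximum possible pixel value (1 for normalised floats,
#'   255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, max_i = 1) {
  if (max_i <= 0) stop("max_i must be positive", call. = FALSE)
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(max_i^2 / m)
}

#' SSIM parameters
#'
#' Stabilising constants and local window for the structural similarity
#' index. Defaults follow the common convention: `k1 = 0.01`, `k2 = 0.03`,
#' an 11x11 Gaussian window with sigma 1.5, dynamic range `L = 1`.
#'
#' @param k1,k2 small positive stabilisers; `c1 = (k1*L)^2`,
#'   `c2 = (k2*L)^2`.
#' @param window `"gaussian"` or `"uniform"`.
#' @param size odd window side length.
#' @param sigma Gaussian window standard deviation (ignored for uniform).
#' @param L dynamic range of the images.
#' @return a list of class `ssim_params`.
#' @export
ssim_params <- function(k1 = 0.01, k2 = 0.03, window = c("gaussian", "uniform"),
                        size = 11L, sigma = 1.5, L = 1) {
  window <- match.arg(window)
  if (k1 <= 0 || k2 <= 0 || L <= 0)
    stop("k1, k2 and L must be positive", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, window = window, size = as.integer(size),
                 sigma = sigma, L = L), class = "ssim_params")
}

ssim_window <- function(params) {
  s <- params$size
  if (params$window == "uniform") {
    w1 <- rep(1 / s, s)
  } else {
    r <- (s - 1) / 2
    w1 <- exp(-(seq(-r, r))^2 / (2 * params$sigma^2))
    w1 <- w1 / sum(w1)
  }
  w1
}

# valid-mode separable windowed filtering: rows of Wr hold the window taps
filter_valid <- function(img, w1) {
  s <- length(w1)
  n <- nrow(img); m <- ncol(img)
  Wr <- matrix(0, n - s + 1L, n)
  for (i in seq_len(n - s + 1L)) Wr[i, i:(i + s - 1L)] <- w1
  Wc <- matrix(0, m - s + 1L, m)
  for (i in seq_len(m - s + 1L)) Wc[i, i:(i + s - 1L)] <- w1
  Wr %*% img %*% t(Wc)
}

#' Structural similarity index
#'
#' Windowed SSIM: local means, variances and covariance are computed under
#' the window (valid mode, i.e. windows fully inside the image, no
#' padding), the similarity map
#' `((2*mu_x*mu_y + c1) * (2*sigma_xy + c2)) /
#'  ((mu_x^2 + mu_y^2 + c1) * (sigma_x^2 + sigma_y^2 + c2))`
#' is evaluated per location, and its mean is returned.
#'
#' @param x,y image matrices of identical shape, at least as large as the
#'   window.
#' @param params an [ssim_params()] object.
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, params = ssim_params()) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y)))
    stop("images must have identical shape", call. = FALSE)
  if (nrow(x) < params$size || ncol(x) < params$size)
    stop("image smaller than the SSIM window", call. = FALSE)
  c1 <- (params$k1 * params$L)^2
  c2 <- (params$k2 * params$L)^2
  w1 <- ssim_window(params)
  mu_x <- filter_valid(x, w1)
  mu_y <- filter_valid(y, w1)
  sxx <- filter_valid(x * x, w1) - mu_x^2
  syy <- filter_valid(y * y, w1) - mu_y^2
  sxy <- filter_valid(x * y, w1) - mu_x * mu_y
  smap <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(smap)
}
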