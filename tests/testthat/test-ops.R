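test_that("conv2d matches a naive direct convolution", {
  set.seed(11)
  x <- array(rnorm(9 * 7 * 3 * 2), c(9, 7, 3, 2))
  for (spec in list(list(k = 3L, s = 1L, p = 1L), list(k = 1L, s = 1L, p = 0L),
                    list(k = 3L, s = 2L, p = 1L))) {
    w <- array(rnorm(spec$k^2 * 3 * 4), c(spec$k, spec$k, 3, 4))
    b <- rnorm(4)
    got <- medsr:::conv_fwd(x, w, b, stride = spec$s, pad = spec$p)
    want <- naive_conv2d(x, w, b, stride = spec$s, pad = spec$p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("conv2d backward agrees with finite differences", {
  set.seed(12)
  x <- array(rnorm(5 * 4 * 2 * 2), c(5, 4, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  gy <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
  loss_x <- function(xv) sum(medsr:::conv_fwd(array(xv, dim(x)), w, b) * gy)
  loss_w <- function(wv) sum(medsr:::conv_fwd(x, array(wv, dim(w)), b) * gy)
  loss_b <- function(bv) sum(medsr:::conv_fwd(x, w, bv) * gy)
  bw <- medsr:::conv_bwd(x, w, gy)
  expect_equal(as.numeric(bw$gx), as.numeric(numeric_grad(loss_x, x)),
               tolerance = 1e-6)
  expect_equal(as.numeric(bw$gw), as.numeric(numeric_grad(loss_w, w)),
               tolerance = 1e-6)
  expect_equal(as.numeric(bw$gb), as.numeric(numeric_grad(loss_b, b)),
               tolerance = 1e-6)
})

test_that("max pooling selects window maxima and routes gradients to them", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  pl <- medsr:::pool_fwd(x, kernel = 2L, stride = 2L, pad = 0L)
  expect_equal(matrix(pl$y[, , 1, 1], 2, 2), matrix(c(6, 8, 14, 16), 2, 2))
  gy <- array(1, c(2, 2, 1, 1))
  gx <- medsr:::pool_bwd(pl$argmax, gy, 4L, 4L)
  expect_equal(sum(gx), 4)
  expect_equal(gx[2, 2, 1, 1], 1) # position of value 6
  # size-preserving 3x3/stride-1/pad-1 pooling keeps a constant map constant
  cst <- array(0.4, c(6, 5, 2, 1))
  pl2 <- medsr:::pool_fwd(cst, kernel = 3L, stride = 1L, pad = 1L)
  expect_equal(pl2$y, cst)
  # gradient check through argmax routing
  set.seed(13)
  xr <- array(rnorm(6 * 6 * 2 * 1), c(6, 6, 2, 1))
  gyr <- array(rnorm(6 * 6 * 2 * 1), c(6, 6, 2, 1))
  plr <- medsr:::pool_fwd(xr, kernel = 3L, stride = 1L, pad = 1L)
  gxr <- medsr:::pool_bwd(plr$argmax, gyr, 6L, 6L)
  fd <- numeric_grad(function(v) {
    sum(medsr:::pool_fwd(array(v, dim(xr)), 3L, 1L, 1L)$y * gyr)
  }, xr, eps = 1e-7)
  expect_equal(as.numeric(gxr), as.numeric(fd), tolerance = 1e-5)
})

test_that("pixel shuffle rearranges r^2*m channels into r-times-larger maps", {
  set.seed(14)
  x <- array(rnorm(3 * 5 * 8 * 2), c(3, 5, 8, 2))
  y <- medsr:::pixel_shuffle(x, 2L)
  expect_equal(dim(y), c(6L, 10L, 2L, 2L))
  # unshuffle is the exact inverse
  expect_equal(medsr:::pixel_unshuffle(y, 2L), x)
  # energy is preserved (pure rearrangement)
  expect_equal(sum(y^2), sum(x^2))
  # a constant-per-channel input yields an interleaving of those constants
  xc <- array(0, c(2, 2, 4, 1))
  for (c in 1:4) xc[, , c, ] <- c
  yc <- medsr:::pixel_shuffle(xc, 2L)
  expect_equal(sort(unique(as.numeric(yc))), as.numeric(1:4))
  expect_equal(dim(yc), c(4L, 4L, 1L, 1L))
})

test_that("bilinear resampling restores exact sizes and backs propagates adjointly", {
  set.seed(15)
  x <- array(rnorm(4 * 3 * 2 * 1), c(4, 3, 2, 1))
  up <- medsr:::bilinear_fwd(x, 17L, 13L)
  expect_equal(dim(up$y), c(17L, 13L, 2L, 1L))
  # adjoint identity: <Ax, y> == <x, A^T y>
  gy <- array(rnorm(17 * 13 * 2 * 1), c(17, 13, 2, 1))
  gx <- medsr:::bilinear_bwd(up, gy)
  expect_equal(sum(up$y * gy), sum(x * gx), tolerance = 1e-10)
  # constants are reproduced exactly
  cst <- array(0.3, c(5, 5, 1, 1))
  expect_equal(medsr:::bilinear_fwd(cst, 12L, 9L)$y,
               array(0.3, c(12, 9, 1, 1)))
})

test_that("bicubic resampling preserves constants and linear ramps", {
  cst <- matrix(0.7, 16, 16)
  expect_equal(medsr:::resize2d(cst, 32, 32), matrix(0.7, 32, 32),
               tolerance = 1e-12)
  expect_equal(medsr:::resize2d(cst, 8, 8), matrix(0.7, 8, 8),
               tolerance = 1e-12)
  # linear ramp: interior of the upscaled image must match the closed-form
  # ramp evaluated at the half-pixel-centred source coordinates
  ramp <- matrix(rep(seq_len(32), each = 32), 32, 32) # ramp along columns
  up <- medsr:::resize2d(ramp, 64, 64)
  src <- (seq_len(64) - 0.5) * 32 / 64 - 0.5 # 0-based source coords
  want <- src + 1 # ramp value at fractional position
  interior <- 5:60
  expect_equal(up[16, interior], want[interior], tolerance = 1e-9)
})

test_that("batch norm backward agrees with finite differences", {
  set.seed(16)
  x <- array(rnorm(4 * 3 * 2 * 2), c(4, 3, 2, 2))
  gamma <- rnorm(2, 1, 0.1)
  beta <- rnorm(2, 0, 0.1)
  gy <- array(rnorm(length(x)), dim(x))
  fw <- medsr:::bn_fwd(x, gamma, beta, numeric(2), rep(1, 2), training = TRUE)
  bw <- medsr:::bn_bwd(fw, gamma, gy)
  fd_x <- numeric_grad(function(v) {
    sum(medsr:::bn_fwd(array(v, dim(x)), gamma, beta, numeric(2), rep(1, 2),
                       TRUE)$y * gy)
  }, x, eps = 1e-6)
  expect_equal(as.numeric(bw$gx), as.numeric(fd_x), tolerance = 1e-4)
  fd_g <- numeric_grad(function(v) {
    sum(medsr:::bn_fwd(x, v, beta, numeric(2), rep(1, 2), TRUE)$y * gy)
  }, gamma)
  expect_equal(as.numeric(bw$ggamma), as.numeric(fd_g), tolerance = 1e-5)
  expect_equal(as.numeric(bw$gbeta), as.numeric(numeric_grad(function(v) {
    sum(medsr:::bn_fwd(x, gamma, v, numeric(2), rep(1, 2), TRUE)$y * gy)
  }, beta)), tolerance = 1e-5)
})

test_that("gaussian blur preserves constants and mass on interior content", {
  cst <- matrix(0.25, 20, 20)
  expect_equal(gauss_blur(cst, 1.3), cst, tolerance = 1e-12)
  expect_identical(gauss_blur(cst, 0), cst)
  # an interior delta keeps total mass (kernel normalised, replicate pad)
  img <- matrix(0, 21, 21)
  img[11, 11] <- 1
  expect_equal(sum(gauss_blur(img, 1.0)), 1, tolerance = 1e-12)
})
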