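# Shared fixtures and independent oracles used across the suite.

# Naive direct convolution (zero padding), independent of the im2col path.
naive_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[4]
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1L
  y <- array(0, c(Ho, Wo, cout, d[4]))
  for (bi in seq_len(d[4])) for (co in seq_len(cout))
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- b[co]
      for (ci in seq_len(d[3])) for (kh in seq_len(k)) for (kw in seq_len(k)) {
        hi <- (ho - 1L) * stride - pad + kh
        wi <- (wo - 1L) * stride - pad + kw
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
          acc <- acc + x[hi, wi, ci, bi] * w[kh, kw, ci, co]
      }
      y[ho, wo, co, bi] <- acc
    }
  y
}

# Central-difference gradient of a scalar-valued function at x.
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Small config for fast structural tests.
tiny_config <- function(scale = 2L, seed = 7L, ...) {
  sr_config(scale = scale, feature_width = 8L, num_blocks = 1L,
            esa_reduction = 4L, head_width = 4L, head_width2 = 4L,
            seed = seed, ...)
}

zero_model <- function(config = tiny_config()) {
  m <- sr_build(config)
  m$params <- lapply(m$params, function(p) lapply(p, function(a) {
    a[] <- 0
    a
  }))
  m
}

rand_image <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}
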