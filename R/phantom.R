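#' Phantom specification
#'
#' Parameters for the seeded synthetic image generator. Two modalities are
#' emulated: `ct_mri_like` (512x512 by default) renders piecewise-smooth
#' anatomy as superposed ellipses with distinct intensities over a dark
#' background plus a mild smooth bias field, in the style of brain
#' phantoms; `ultrasound_like` (256x256 by default) renders low-frequency
#' anatomy modulated by multiplicative speckle with a few bright
#' ellipsoidal inclusions, in the style of kidney-stone scans.
#'
#' @param modality `"ct_mri_like"` or `"ultrasound_like"`.
#' @param size square image side in pixels (>= 64, divisible by 4 so both
#'   2x and 4x degradations apply); defaults to 512 for `ct_mri_like` and
#'   256 for `ultrasound_like`.
#' @param n_ellipses number of anatomy ellipses (inclusions for
#'   ultrasound).
#' @param speckle_strength multiplicative speckle contrast in `[0, 1]`
#'   (ultrasound only).
#' @param seed integer seed; generation is bit-reproducible per seed.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(modality = c("ct_mri_like", "ultrasound_like"),
                         size = NULL, n_ellipses = NULL,
                         speckle_strength = 0.5, seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(size)) size <- if (modality == "ct_mri_like") 512L else 256L
  size <- as.integer(size)
  if (size < 64L) stop("size must be >= 64", call. = FALSE)
  if (size %% 4L != 0L)
    stop("size must be divisible by 4 so both scales apply", call. = FALSE)
  if (is.null(n_ellipses))
    n_ellipses <- if (modality == "ct_mri_like") 9L else 3L
  structure(list(modality = modality, size = size,
                 n_ellipses = as.integer(n_ellipses),
                 speckle_strength = speckle_strength,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# mask of a rotated ellipse on the [-1, 1]^2 grid
ellipse_mask <- function(X, Y, cx, cy, a, b, theta) {
  xr <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  yr <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate a synthetic phantom image
#'
#' @param spec a [phantom_spec()].
#' @return `size x size` matrix with intensities in `[0, 1]`, deterministic
#'   given `spec` (including its seed).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  n <- spec$size
  ax <- seq(-1, 1, length.out = n)
  X <- matrix(ax, n, n, byrow = TRUE)
  Y <- matrix(ax, n, n)
  if (spec$modality == "ct_mri_like") {
    img <- matrix(0.02, n, n)
    # enclosing "skull" ellipse
    outer_m <- ellipse_mask(X, Y, 0, 0, 0.92, 0.88, 0)
    img[outer_m] <- 0.85
    inner_m <- ellipse_mask(X, Y, 0, 0, 0.86, 0.82, 0)
    img[inner_m] <- 0.25
    for (i in seq_len(spec$n_ellipses)) {
      cx <- stats::runif(1, -0.45, 0.45)
      cy <- stats::runif(1, -0.45, 0.45)
      a <- stats::runif(1, 0.06, 0.45)
      b <- stats::runif(1, 0.06, 0.45)
      th <- stats::runif(1, 0, pi)
      val <- stats::runif(1, 0.1, 0.95)
      m <- ellipse_mask(X, Y, cx, cy, a, b, th) & inner_m
      img[m] <- 0.85 * val + 0.15 * img[m]
    }
    cf <- stats::runif(4, -1, 1)
    bias <- 1 + 0.08 * (cf[1] * X + cf[2] * Y + cf[3] * X * Y +
                          cf[4] * (X^2 - Y^2))
    img <- gauss_blur(img * bias, 0.7) # soften ideal edges slightly
  } else {
    # smooth anatomy field
    base <- gauss_blur(matrix(stats::rnorm(n * n), n, n), n / 16)
    base <- 0.25 + 0.3 * (base - min(base)) / (max(base) - min(base) + 1e-12)
    # hypoechoic region (e.g. renal pelvis)
    m <- ellipse_mask(X, Y, stats::runif(1, -0.3, 0.3),
                      stats::runif(1, -0.3, 0.3), 0.35, 0.22,
                      stats::runif(1, 0, pi))
    base[m] <- base[m] * 0.45
    # bright ellipsoidal inclusions (stones)
    for (i in seq_len(spec$n_ellipses)) {
      mi <- ellipse_mask(X, Y, stats::runif(1, -0.5, 0.5),
                         stats::runif(1, -0.5, 0.5),
                         stats::runif(1, 0.02, 0.06),
                         stats::runif(1, 0.02, 0.06),
                         stats::runif(1, 0, pi))
      base[mi] <- 0.9
    }
    # multiplicative speckle: smoothed exponential field, unit mean
    sp <- gauss_blur(matrix(stats::rexp(n * n), n, n), 0.8)
    sp <- sp / mean(sp)
    img <- base * (1 + spec$speckle_strength * (sp - 1))
    # mild depth attenuation
    img <- img * (1 - 0.25 * (Y + 1) / 2)
  }
  pmin(pmax(img, 0), 1)
}

#' Degradation specification
#'
#' The forward HR -> LR process used to create training pairs: optional
#' Gaussian blur, bicubic (anti-aliased) downsampling by `scale`, optional
#' additive Gaussian noise, then clipping to `[0, 1]`.
#'
#' @param scale downsampling factor, 2 or 4.
#' @param blur_sigma Gaussian blur sigma in HR pixels (0 = skip).
#' @param noise_sigma additive noise sigma on the `[0, 1]` scale (0 =
#'   skip).
#' @param downsample_kernel only `"bicubic"` is supported.
#' @param seed seed for the noise draw.
#' @return a list of class `degradation_spec`.
#' @export
degradation_spec <- function(scale = 2L, blur_sigma = 0, noise_sigma = 0,
                             downsample_kernel = "bicubic", seed = 1L) {
  if (!scale %in% c(2L, 4L)) stop("scale must be 2 or 4", call. = FALSE)
  if (downsample_kernel != "bicubic")
    stop("only bicubic downsampling is supported", call. = FALSE)
  if (blur_sigma < 0 || noise_sigma < 0)
    stop("sigmas must be >= 0", call. = FALSE)
  structure(list(scale = as.integer(scale), blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma,
                 downsample_kernel = downsample_kernel,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a high-resolution image to its low-resolution counterpart
#'
#' @param hr HR image matrix with dims divisible by `spec$scale`.
#' @param spec a [degradation_spec()].
#' @return LR matrix of size `dim(hr) / scale`, clipped to `[0, 1]`.
#' @export
degrade <- function(hr, spec = degradation_spec()) {
  hr <- as.matrix(hr)
  if (any(dim(hr) %% spec$scale != 0L))
    stop("HR dimensions must be divisible by the scale", call. = FALSE)
  x <- hr
  if (spec$blur_sigma > 0) x <- gauss_blur(x, spec$blur_sigma)
  lr <- resize2d(x, nrow(hr) %/% spec$scale, ncol(hr) %/% spec$scale,
                 kernel = "cubic", antialias = TRUE)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    lr <- lr + matrix(stats::rnorm(length(lr), 0, spec$noise_sigma),
                      nrow(lr), ncol(lr))
  }
  pmin(pmax(lr, 0), 1)
}

#' Bicubic upscaling baseline
#'
#' Standard bicubic (Keys, a = -1/2) interpolation to `scale` times the
#' input size; the zero-parameter baseline in all benchmarks.
#'
#' @param lr LR image matrix.
#' @param scale 2 or 4.
#' @return upscaled matrix.
#' @export
bicubic_upscale <- function(lr, scale) {
  if (!scale %in% c(2L, 4L)) stop("scale must be 2 or 4", call. = FALSE)
  resize2d(as.matrix(lr), nrow(lr) * scale, ncol(lr) * scale,
           kernel = "cubic", antialias = FALSE)
}

#' Bicubic baseline "model"
#'
#' A parameter-free model object applying [bicubic_upscale()], so the
#' baseline can be evaluated through the same interface as trained models.
#'
#' @param scale 2 or 4.
#' @return object of class `bicubic_sr`.
#' @export
bicubic_sr <- function(scale = 2L) {
  structure(list(config = list(scale = as.integer(scale))),
            class = "bicubic_sr")
}

#' @export
predict.bicubic_sr <- function(object, lr, ...) {
  bicubic_upscale(as.matrix(as_map4(lr)[, , 1, 1]), object$config$scale)
}

#' Build a paired LR/HR synthetic dataset
#'
#' Generates `n` phantoms with seeds `spec$seed .. spec$seed + n - 1`,
#' degrades each to its LR counterpart (noise seeds offset the same way),
#' and splits by index into train/val/test as
#' `floor(0.8 n) / floor(0.1 n) / rest`.
#'
#' @param n number of pairs (>= 1).
#' @param phantom a [phantom_spec()] (its seed is the base seed).
#' @param degr a [degradation_spec()].
#' @return object of class `sr_dataset`: list with `pairs` (each holding
#'   `hr`, `lr`, `seed`), `split` (character vector), and `scale`.
#' @export
make_dataset <- function(n, phantom = phantom_spec(),
                         degr = degradation_spec()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- phantom
    ps$seed <- phantom$seed + i - 1L
    hr <- make_phantom(ps)
    ds <- degr
    ds$seed <- degr$seed + i - 1L
    pairs[[i]] <- list(hr = hr, lr = degrade(hr, ds), seed = ps$seed)
  }
  n_train <- floor(0.8 * n)
  n_val <- floor(0.1 * n)
  split <- rep("test", n)
  if (n_train > 0) split[seq_len(n_train)] <- "train"
  if (n_val > 0) split[n_train + seq_len(n_val)] <- "val"
  structure(list(pairs = pairs, split = split, scale = degr$scale,
                 phantom = phantom, degradation = degr),
            class = "sr_dataset")
}

#' @export
print.sr_dataset <- function(x, ...) {
  cat(sprintf("<sr_dataset> %d pairs (%s), scale %dx, HR %dx%d\n",
              length(x$pairs),
              paste(table(factor(x$split, c("train", "val", "test"))),
                    collapse = "/"),
              x$scale, nrow(x$pairs[[1]]$hr), ncol(x$pairs[[1]]$hr)))
  invisible(x)
}
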