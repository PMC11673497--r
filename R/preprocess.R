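#' Augmentation specification
#'
#' One random geometric transform (quarter-turn rotation and/or flips) and
#' photometric jitter (brightness shift, contrast scaling about the HR
#' mean) applied identically to both images of an LR/HR pair, plus
#' optional Gaussian noise/blur emulating acquisition imperfections.
#' Rotations are restricted to quarter-turns so no resampling is involved
#' and pair alignment stays exact.
#'
#' @param rotations allowed quarter-turns, subset of `c(0, 90, 180, 270)`.
#' @param hflip,vflip allow horizontal/vertical flips (each drawn with
#'   probability 1/2 when allowed).
#' @param brightness_delta max absolute additive shift (drawn uniformly
#'   from `[-d, d]`).
#' @param contrast_range max relative contrast change `rho`: factor drawn
#'   from `[1 - rho, 1 + rho]`, applied about the HR mean.
#' @param gauss_noise_sigma,gauss_blur_sigma acquisition-imperfection
#'   jitter (0 disables).
#' @param noise_on `"lr"` (default; simulates low-quality acquisition) or
#'   `"both"`.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as in the training loop).
#' @return a list of class `augment_spec`.
#' @export
augment_spec <- function(rotations = c(0, 90, 180, 270), hflip = TRUE,
                         vflip = TRUE, brightness_delta = 0,
                         contrast_range = 0, gauss_noise_sigma = 0,
                         gauss_blur_sigma = 0, noise_on = c("lr", "both"),
                         seed = NULL) {
  if (!all(rotations %in% c(0, 90, 180, 270)))
    stop("rotations must be quarter-turns", call. = FALSE)
  noise_on <- match.arg(noise_on)
  structure(list(rotations = rotations, hflip = isTRUE(hflip),
                 vflip = isTRUE(vflip), brightness_delta = brightness_delta,
                 contrast_range = contrast_range,
                 gauss_noise_sigma = gauss_noise_sigma,
                 gauss_blur_sigma = gauss_blur_sigma, noise_on = noise_on,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "augment_spec")
}

rot90cw <- function(m, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

#' Augment an aligned LR/HR pair
#'
#' Samples one geometric transform and photometric jitter from the spec
#' and applies it so that pair alignment is preserved; outputs are clipped
#' to `[0, 1]`.
#'
#' @param lr,hr aligned pair; `dim(hr)` must be an integer multiple of
#'   `dim(lr)`.
#' @param spec an [augment_spec()].
#' @return list with transformed `lr` and `hr`.
#' @export
augment_pair <- function(lr, hr, spec = augment_spec()) {
  lr <- as.matrix(lr); hr <- as.matrix(hr)
  if (any(dim(hr) %% dim(lr) != 0L) ||
      (dim(hr)[1] %/% dim(lr)[1]) != (dim(hr)[2] %/% dim(lr)[2]))
    stop("misaligned pair: HR dims must be an integer multiple of LR dims",
         call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  k <- sample(spec$rotations, 1L) %/% 90L
  do_h <- spec$hflip && stats::runif(1) < 0.5
  do_v <- spec$vflip && stats::runif(1) < 0.5
  geo <- function(m) {
    m <- rot90cw(m, k)
    if (do_h) m <- m[, ncol(m):1, drop = FALSE]
    if (do_v) m <- m[nrow(m):1, , drop = FALSE]
    m
  }
  lr <- geo(lr); hr <- geo(hr)
  if (spec$brightness_delta > 0 || spec$contrast_range > 0) {
    delta <- if (spec$brightness_delta > 0)
      stats::runif(1, -spec$brightness_delta, spec$brightness_delta) else 0
    fac <- if (spec$contrast_range > 0)
      stats::runif(1, 1 - spec$contrast_range, 1 + spec$contrast_range) else 1
    anchor <- mean(hr) # shared anchor keeps the pair photometrically aligned
    lr <- anchor + fac * (lr - anchor) + delta
    hr <- anchor + fac * (hr - anchor) + delta
  }
  if (spec$gauss_blur_sigma > 0) {
    lr <- gauss_blur(lr, spec$gauss_blur_sigma)
    if (spec$noise_on == "both") hr <- gauss_blur(hr, spec$gauss_blur_sigma)
  }
  if (spec$gauss_noise_sigma > 0) {
    lr <- lr + matrix(stats::rnorm(length(lr), 0, spec$gauss_noise_sigma),
                      nrow(lr))
    if (spec$noise_on == "both")
      hr <- hr + matrix(stats::rnorm(length(hr), 0, spec$gauss_noise_sigma),
                        nrow(hr))
  }
  list(lr = pmin(pmax(lr, 0), 1), hr = pmin(pmax(hr, 0), 1))
}

#' Normalise an image to [0, 1]
#'
#' @param img numeric image.
#' @param value_range declared domain, e.g. `c(0, 255)` for 8-bit input.
#' @return image mapped to `[0, 1]`.
#' @export
normalize_image <- function(img, value_range = c(0, 255)) {
  if (length(value_range) != 2 || value_range[2] <= value_range[1])
    stop("unknown value range", call. = FALSE)
  (img - value_range[1]) / (value_range[2] - value_range[1])
}

#' Invert [normalize_image()]
#'
#' @param img image in `[0, 1]`.
#' @param value_range target domain.
#' @param round_to_int round the result (exact integer round-trip for
#'   8-bit data).
#' @return image on the original scale.
#' @export
denormalize_image <- function(img, value_range = c(0, 255),
                              round_to_int = TRUE) {
  out <- img * (value_range[2] - value_range[1]) + value_range[1]
  if (round_to_int) out <- round(out)
  out
}

#' Extract aligned random patch pairs
#'
#' @param lr,hr aligned pair (HR = scale x LR).
#' @param patch LR patch side; the HR patch is `scale * patch` at the
#'   scaled offset.
#' @param n number of patches.
#' @param seed optional seed (`NULL`: current RNG stream).
#' @return list of `n` lists with `lr`, `hr` patch matrices.
#' @export
extract_patches <- function(lr, hr, patch, n, seed = NULL) {
  lr <- as.matrix(lr); hr <- as.matrix(hr)
  r <- nrow(hr) %/% nrow(lr)
  if (patch > nrow(lr) || patch > ncol(lr))
    stop("patch larger than the LR image", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    oy <- sample.int(nrow(lr) - patch + 1L, 1L) - 1L
    ox <- sample.int(ncol(lr) - patch + 1L, 1L) - 1L
    out[[i]] <- list(
      lr = lr[oy + seq_len(patch), ox + seq_len(patch), drop = FALSE],
      hr = hr[r * oy + seq_len(r * patch), r * ox + seq_len(r * patch),
              drop = FALSE])
  }
  out
}
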