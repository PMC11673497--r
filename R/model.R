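#' Model configuration
#'
#' Collects every architecture hyperparameter of the residual
#' super-resolution network: a shallow 3x3 convolution lifts the
#' single-channel input to `feature_width` channels, `num_blocks` modified
#' residual blocks refine the features, a 3x3 convolution plus a long skip
#' from the shallow features closes the trunk, and a sub-pixel
#' (pixel-shuffle) head upsamples by `scale`.
#'
#' The defaults are the calibrated configuration whose trainable parameter
#' count rounds to the 452K (2x) / 468K (4x) budgets; see
#' [calibrate_width()].
#'
#' @param scale integer upscaling factor, 2 or 4.
#' @param in_channels number of image channels (1 for grayscale medical
#'   images).
#' @param feature_width trunk channel count `C` (>= 4).
#' @param num_blocks number of residual blocks `B` (>= 1).
#' @param esa_reduction divisor for the attention-gate channel squeeze;
#'   must divide `feature_width`.
#' @param use_bn_branch keep the batch-normalised 3x3 branch in each block
#'   (disable for ablation).
#' @param pool_kernel kernel of the size-preserving max pooling inside each
#'   block (odd; stride 1, padding `(pool_kernel-1)/2`).
#' @param head_width sub-pixel head width `m` (channels after the first
#'   pixel shuffle).
#' @param head_width2 width of the second pixel-shuffle stage (4x models
#'   only).
#' @param seed integer seed for deterministic weight initialisation.
#' @return an object of class `sr_config`.
#' @export
sr_config <- function(scale = 2L, in_channels = 1L, feature_width = 40L,
                      num_blocks = 6L, esa_reduction = 8L,
                      use_bn_branch = TRUE, pool_kernel = 3L,
                      head_width = 25L, head_width2 = 18L, seed = 1L) {
  cfg <- list(scale = as.integer(scale), in_channels = as.integer(in_channels),
              feature_width = as.integer(feature_width),
              num_blocks = as.integer(num_blocks),
              esa_reduction = as.integer(esa_reduction),
              use_bn_branch = isTRUE(use_bn_branch),
              pool_kernel = as.integer(pool_kernel),
              head_width = as.integer(head_width),
              head_width2 = as.integer(head_width2),
              seed = as.integer(seed))
  class(cfg) <- "sr_config"
  validate_sr_config(cfg)
  cfg
}

validate_sr_config <- function(cfg) {
  if (!cfg$scale %in% c(2L, 4L))
    stop("scale must be 2 or 4", call. = FALSE)
  if (cfg$feature_width < 4L)
    stop("feature_width must be >= 4", call. = FALSE)
  if (cfg$num_blocks < 1L)
    stop("num_blocks must be >= 1", call. = FALSE)
  if (cfg$feature_width %% cfg$esa_reduction != 0L)
    stop("esa_reduction must divide feature_width", call. = FALSE)
  if (cfg$pool_kernel < 1L || cfg$pool_kernel %% 2L == 0L)
    stop("pool_kernel must be odd and positive", call. = FALSE)
  invisible(cfg)
}

# ---- construction -----------------------------------------------------------

kaiming_uniform <- function(k, cin, cout) {
  fan_in <- k * k * cin
  bound <- sqrt(6 / fan_in)
  array(stats::runif(k * k * cin * cout, -bound, bound), c(k, k, cin, cout))
}

new_conv <- function(env, name, k, cin, cout) {
  env$params[[name]] <- list(w = kaiming_uniform(k, cin, cout),
                             b = numeric(cout))
  env$layers <- rbind(env$layers, data.frame(
    name = name, kind = "conv", kernel = k, cin = cin, cout = cout))
}

new_bn <- function(env, name, c) {
  env$params[[name]] <- list(gamma = rep(1, c), beta = numeric(c))
  env$buffers[[name]] <- list(rmean = numeric(c), rvar = rep(1, c))
  env$layers <- rbind(env$layers, data.frame(
    name = name, kind = "bn", kernel = NA_integer_, cin = c, cout = c))
}

#' Build a super-resolution model
#'
#' Instantiates the network described by an [sr_config()]: shallow 3x3
#' convolution, `num_blocks` residual blocks (each with a batch-normalised
#' and a plain 3x3 branch joined by two concatenation/1x1-fusion stages,
#' size-preserving max pooling, an enhanced spatial attention gate and a
#' block-input skip), a trunk-closing 3x3 convolution with a long skip,
#' and a pixel-shuffle upsampling head (one stage for 2x, two cascaded 2x
#' stages for 4x). Convolution weights use Kaiming-uniform fan-in
#' initialisation seeded from `config$seed`; biases start at zero, batch
#' norm at scale 1 / shift 0.
#'
#' @param config an [sr_config()].
#' @return an object of class `sr_model`.
#' @export
sr_build <- function(config = sr_config()) {
  validate_sr_config(config)
  set.seed(config$seed)
  env <- new.env()
  env$params <- list()
  env$buffers <- list()
  env$layers <- data.frame()
  C <- config$feature_width
  Cr <- C %/% config$esa_reduction
  new_conv(env, "shallow", 3L, config$in_channels, C)
  for (i in seq_len(config$num_blocks)) {
    p <- function(s) paste0("b", i, ".", s)
    new_conv(env, p("c1"), 1L, C, C)
    new_conv(env, p("c2"), 3L, C, C)
    if (config$use_bn_branch) new_bn(env, p("bn2"), C)
    new_conv(env, p("c3"), 3L, C, C)
    new_conv(env, p("c4"), 1L, 2L * C, C)
    new_conv(env, p("c5"), 3L, C, C)
    if (config$use_bn_branch) new_bn(env, p("bn5"), C)
    new_conv(env, p("c6"), 3L, C, C)
    new_conv(env, p("c8"), 1L, 2L * C, C)
    new_conv(env, p("esa.c1"), 1L, C, Cr)
    new_conv(env, p("esa.cf"), 1L, Cr, Cr)
    new_conv(env, p("esa.c2"), 3L, Cr, Cr)
    new_conv(env, p("esa.c3"), 3L, Cr, Cr)
    new_conv(env, p("esa.c4"), 1L, Cr, 1L)
  }
  new_conv(env, "post", 3L, C, C)
  m <- config$head_width
  new_conv(env, "head.u1", 3L, C, 4L * m)
  if (config$scale == 4L) {
    m2 <- config$head_width2
    new_conv(env, "head.u2", 3L, m, 4L * m2)
    new_conv(env, "head.out", 3L, m2, config$in_channels)
  } else {
    new_conv(env, "head.out", 3L, m, config$in_channels)
  }
  model <- list(config = config, params = env$params, buffers = env$buffers,
                layers = env$layers)
  class(model) <- "sr_model"
  model
}

#' @export
print.sr_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sr_model> scale %dx | width %d | blocks %d | esa 1/%d | params %s (%d K)\n",
    cfg$scale, cfg$feature_width, cfg$num_blocks, cfg$esa_reduction,
    format(count_parameters(x), big.mark = ","),
    round(count_parameters(x) / 1000)))
  invisible(x)
}

# ---- parameter counting -----------------------------------------------------

#' Count trainable parameters
#'
#' Number of trainable scalars (convolution weights and biases, batch-norm
#' scales and shifts). The bicubic baseline reports 0.
#'
#' @param model an `sr_model` or `bicubic_sr` object.
#' @return integer count.
#' @export
count_parameters <- function(model) UseMethod("count_parameters")

#' @export
count_parameters.sr_model <- function(model) {
  sum(vapply(model$params,
             function(p) sum(vapply(p, length, integer(1))), numeric(1)))
}

#' @export
count_parameters.bicubic_sr <- function(model) 0L

# Closed-form count used by the calibration search (cheap; no weights
# allocated). Must agree with count_parameters(sr_build(cfg)).
param_count_formula <- function(scale, in_ch, C, B, red, m, m2,
                                use_bn = TRUE) {
  Cr <- C %/% red
  conv <- function(k, ci, co) k * k * ci * co + co
  block <- conv(1, C, C) + 4 * conv(3, C, C) + 2 * conv(1, 2 * C, C) +
    (if (use_bn) 4 * C else 0) +
    conv(1, C, Cr) + conv(1, Cr, Cr) + 2 * conv(3, Cr, Cr) + conv(1, Cr, 1)
  trunk <- conv(3, in_ch, C) + B * block + conv(3, C, C)
  head <- if (scale == 2L) {
    conv(3, C, 4 * m) + conv(3, m, in_ch)
  } else {
    conv(3, C, 4 * m) + conv(3, m, 4 * m2) + conv(3, m2, in_ch)
  }
  trunk + head
}

#' Calibrate the network width to a parameter budget
#'
#' Searches the architecture's free widths so that the trainable parameter
#' count, rounded to the nearest thousand, equals `budget_kparams`. For a
#' 2x model the search runs, in documented order, over the attention
#' squeeze divisor (4, then 8, then 2), the trunk width `C` (ascending
#' multiples of the divisor up to 160) and the head width `m` (ascending,
#' 4..96), at the fixed default depth of 6 blocks; the first satisfying
#' configuration is returned. For a 4x model, pass the calibrated 2x
#' configuration as `trunk`: the trunk and first head stage are reused
#' unchanged and only the second pixel-shuffle stage width `m2` is
#' searched, so the two models share all trunk weights' shapes. Without
#' `trunk`, a 4x calibration searches all widths jointly.
#'
#' @param budget_kparams target size in thousands of parameters.
#' @param scale 2 or 4.
#' @param trunk optional `sr_config` whose trunk (and first head stage) the
#'   4x model must share.
#' @param num_blocks depth used during the search (default 6).
#' @param in_channels image channels (default 1).
#' @return an [sr_config()] meeting the budget.
#' @export
calibrate_width <- function(budget_kparams, scale, trunk = NULL,
                            num_blocks = 6L, in_channels = 1L) {
  if (budget_kparams <= 0) stop("budget must be positive", call. = FALSE)
  if (!scale %in% c(2L, 4L)) stop("scale must be 2 or 4", call. = FALSE)
  hit <- function(p) round(p / 1000) == budget_kparams
  if (!is.null(trunk)) {
    if (scale != 4L)
      stop("a trunk configuration is only meaningful for scale 4",
           call. = FALSE)
    for (m2 in 4:96) {
      p <- param_count_formula(4L, trunk$in_channels, trunk$feature_width,
                               trunk$num_blocks, trunk$esa_reduction,
                               trunk$head_width, m2, trunk$use_bn_branch)
      if (hit(p))
        return(sr_config(scale = 4L, in_channels = trunk$in_channels,
                         feature_width = trunk$feature_width,
                         num_blocks = trunk$num_blocks,
                         esa_reduction = trunk$esa_reduction,
                         use_bn_branch = trunk$use_bn_branch,
                         pool_kernel = trunk$pool_kernel,
                         head_width = trunk$head_width, head_width2 = m2,
                         seed = trunk$seed))
    }
    stop("calibration error: no head width meets the budget", call. = FALSE)
  }
  for (red in c(4L, 8L, 2L)) {
    for (C in seq(red, 160L, by = red)) {
      for (m in 4:min(C, 96L)) { # head never wider than the trunk
        if (scale == 2L) {
          p <- param_count_formula(2L, in_channels, C, num_blocks, red, m, 0L)
          if (hit(p))
            return(sr_config(scale = 2L, in_channels = in_channels,
                             feature_width = C, num_blocks = num_blocks,
                             esa_reduction = red, head_width = m))
        } else {
          for (m2 in 4:96) {
            p <- param_count_formula(4L, in_channels, C, num_blocks, red,
                                     m, m2)
            if (hit(p))
              return(sr_config(scale = 4L, in_channels = in_channels,
                               feature_width = C, num_blocks = num_blocks,
                               esa_reduction = red, head_width = m,
                               head_width2 = m2))
          }
        }
      }
    }
  }
  stop("calibration error: no width meets the budget within search bounds",
       call. = FALSE)
}

#' Save / load a model configuration
#'
#' Serialises an [sr_config()] to YAML or JSON (chosen by file
#' extension), and restores it with validation.
#'
#' @param config an `sr_config`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `path` (save) or the restored `sr_config` (load).
#' @export
save_sr_config <- function(config, path) {
  validate_sr_config(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(config), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE)
  } else {
    stop("config files must be .yaml/.yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' @rdname save_sr_config
#' @export
load_sr_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config files must be .yaml/.yml or .json", call. = FALSE)
  }
  do.call(sr_config, raw[names(raw) %in% names(formals(sr_config))])
}
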