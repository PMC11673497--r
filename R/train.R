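#' Training options
#'
#' Optimiser and sampling hyperparameters for [sr_train()]. The defaults
#' follow common lightweight-SR practice: Adam (0.9, 0.999), learning rate
#' 5e-4 halved at the midpoint of training, batches of 16 LR patches of
#' side 48.
#'
#' @param steps number of optimisation steps (>= 0; 0 returns the model
#'   unchanged).
#' @param batch_size patches per step.
#' @param patch_size LR patch side in pixels.
#' @param learning_rate initial Adam step size.
#' @param lr_schedule `"constant"` or `"step"` (multiply by `gamma` every
#'   `every` steps; default halves once at the midpoint).
#' @param gamma,every step-schedule parameters; `every = NULL` means half
#'   of `steps`.
#' @param beta1,beta2 Adam moment decays.
#' @param seed RNG seed covering patch sampling, augmentation draws and
#'   any noise.
#' @param validate_every validate (and snapshot the best model) every this
#'   many steps; `0` disables validation.
#' @param augment optional [augment_spec()] applied to each sampled pair
#'   (`NULL` disables augmentation).
#' @return a list of class `train_options`.
#' @export
train_options <- function(steps = 1000L, batch_size = 16L, patch_size = 48L,
                          learning_rate = 5e-4,
                          lr_schedule = c("step", "constant"), gamma = 0.5,
                          every = NULL, beta1 = 0.9, beta2 = 0.999,
                          seed = 1L, validate_every = 100L, augment = NULL) {
  lr_schedule <- match.arg(lr_schedule)
  if (steps < 0) stop("steps must be >= 0", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 learning_rate = learning_rate, lr_schedule = lr_schedule,
                 gamma = gamma, every = every, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed),
                 validate_every = as.integer(validate_every),
                 augment = augment),
            class = "train_options")
}

adam_init <- function(params) {
  lapply(params, function(p) lapply(p, function(a) {
    z <- a; z[] <- 0
    list(m = z, v = z)
  }))
}

adam_step <- function(params, grads, state, lr, beta1, beta2, t,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    for (part in names(grads[[nm]])) {
      g <- grads[[nm]][[part]]
      st <- state[[nm]][[part]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      state[[nm]][[part]] <- st
      params[[nm]][[part]] <- params[[nm]][[part]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

sample_batch <- function(data, idx_train, patch, batch, scale, augment) {
  p <- patch
  x <- array(0, c(p, p, 1L, batch))
  t <- array(0, c(scale * p, scale * p, 1L, batch))
  for (b in seq_len(batch)) {
    pair <- data$pairs[[sample(idx_train, 1L)]]
    lr <- pair$lr; hr <- pair$hr
    if (!is.null(augment)) {
      aug <- augment_pair(lr, hr, augment)
      lr <- aug$lr; hr <- aug$hr
    }
    oy <- sample.int(nrow(lr) - p + 1L, 1L) - 1L
    ox <- sample.int(ncol(lr) - p + 1L, 1L) - 1L
    x[, , 1L, b] <- lr[oy + seq_len(p), ox + seq_len(p)]
    t[, , 1L, b] <- hr[scale * oy + seq_len(scale * p),
                       scale * ox + seq_len(scale * p)]
  }
  list(x = x, t = t)
}

#' Train a super-resolution model by MSE minimisation
#'
#' Minimises the mean squared error `1/N * sum((y - y')^2)` between model
#' outputs and HR targets over randomly sampled aligned patch batches,
#' using Adam. Training is deterministic given the seed (single device).
#' If the dataset has a validation split and `validate_every > 0`, the
#' returned model is the checkpoint with the best validation PSNR;
#' otherwise the final state.
#'
#' @param model an [sr_build()] model whose scale matches the dataset.
#' @param data an [make_dataset()] dataset (non-empty train split).
#' @param opts a [train_options()].
#' @return list with `model` (best checkpoint), `final` (last state),
#'   `history` (class `train_history`: per-step `loss`, `lr`, and a
#'   data.frame `validation` of step/psnr/ssim).
#' @export
sr_train <- function(model, data, opts = train_options()) {
  if (!inherits(data, "sr_dataset")) stop("data must be an sr_dataset",
                                          call. = FALSE)
  scale <- model$config$scale
  if (scale != data$scale)
    stop("model scale does not match dataset scale", call. = FALSE)
  idx_train <- which(data$split == "train")
  if (length(idx_train) == 0) stop("empty training split", call. = FALSE)
  idx_val <- which(data$split == "val")
  history <- list(loss = numeric(0), lr = numeric(0),
                  validation = data.frame(step = integer(0), psnr = numeric(0),
                                          ssim = numeric(0)))
  if (opts$steps == 0L)
    return(list(model = model, final = model,
                history = structure(history, class = "train_history")))
  set.seed(opts$seed)
  state <- adam_init(model$params)
  every <- if (is.null(opts$every)) max(1L, opts$steps %/% 2L) else
    as.integer(opts$every)
  best <- list(psnr = -Inf, params = NULL, buffers = NULL)
  losses <- numeric(opts$steps)
  lrs <- numeric(opts$steps)
  for (step in seq_len(opts$steps)) {
    lr_t <- if (opts$lr_schedule == "step")
      opts$learning_rate * opts$gamma^((step - 1L) %/% every) else
        opts$learning_rate
    batch <- sample_batch(data, idx_train, opts$patch_size, opts$batch_size,
                          scale, opts$augment)
    out <- model_fwd(model, batch$x, training = TRUE)
    model$buffers <- out$buffers
    resid <- out$y - batch$t
    loss <- mean(resid^2)
    if (!is.finite(loss))
      stop(sprintf("training aborted: non-finite loss at step %d", step),
           call. = FALSE)
    losses[step] <- loss
    lrs[step] <- lr_t
    bw <- model_bwd(model, out$cache, 2 * resid / length(resid))
    upd <- adam_step(model$params, bw$grads, state, lr_t, opts$beta1,
                     opts$beta2, step)
    model$params <- upd$params
    state <- upd$state
    if (opts$validate_every > 0L && length(idx_val) > 0L &&
        (step %% opts$validate_every == 0L || step == opts$steps)) {
      ev <- evaluate(model, data, split = "val")
      history$validation <- rbind(history$validation,
                                  data.frame(step = step, psnr = ev$psnr_db,
                                             ssim = ev$ssim))
      if (ev$psnr_db > best$psnr)
        best <- list(psnr = ev$psnr_db, params = model$params,
                     buffers = model$buffers)
    }
  }
  history$loss <- losses
  history$lr <- lrs
  final <- model
  if (!is.null(best$params)) {
    model$params <- best$params
    model$buffers <- best$buffers
  }
  list(model = model, final = final,
       history = structure(history, class = "train_history"))
}

#' Evaluate a model on a dataset split
#'
#' Mean PSNR and mean SSIM of model outputs against HR ground truth over
#' the chosen split, plus parameter count and measured per-image runtime
#' (informational; hardware-dependent).
#'
#' @param model an `sr_model` or [bicubic_sr()] baseline.
#' @param data an `sr_dataset`.
#' @param split `"test"` (default), `"val"`, `"train"`, or `"all"`.
#' @param max_i dynamic range of the images (1 for normalised data).
#' @param model_name label used in reports.
#' @return one metric-report row (list): `model_name`, `params_k`,
#'   `runtime_ms`, `psnr_db`, `ssim`, `n_images`.
#' @export
evaluate <- function(model, data, split = "test", max_i = 1,
                     model_name = class(model)[1]) {
  idx <- if (split == "all") seq_along(data$pairs) else
    which(data$split == split)
  if (length(idx) == 0) stop("empty evaluation split", call. = FALSE)
  scale <- model$config$scale
  if (scale != data$scale)
    stop("model scale does not match dataset scale", call. = FALSE)
  sp <- ssim_params(L = max_i)
  ps <- numeric(length(idx)); ss <- numeric(length(idx))
  tms <- numeric(length(idx))
  for (j in seq_along(idx)) {
    pair <- data$pairs[[idx[j]]]
    t0 <- proc.time()[["elapsed"]]
    sr <- predict(model, pair$lr)
    tms[j] <- (proc.time()[["elapsed"]] - t0) * 1000
    ps[j] <- psnr(sr, pair$hr, max_i = max_i)
    ss[j] <- ssim(sr, pair$hr, sp)
  }
  list(model_name = model_name,
       params_k = as.integer(round(count_parameters(model) / 1000)),
       runtime_ms = mean(tms), psnr_db = mean(ps), ssim = mean(ss),
       n_images = length(idx))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a flat named-weight archive with the configuration (and
#' optionally training options/history) embedded.
#'
#' @param model an `sr_model`.
#' @param path file path (`.rds`).
#' @param opts,history optional metadata stored alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, opts = NULL, history = NULL) {
  saveRDS(list(config = model$config, params = model$params,
               buffers = model$buffers, layers = model$layers,
               opts = opts, history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- list(config = ck$config, params = ck$params,
                buffers = ck$buffers, layers = ck$layers)
  class(model) <- "sr_model"
  attr(model, "opts") <- ck$opts
  attr(model, "history") <- ck$history
  model
}
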