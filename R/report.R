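#' Benchmark the network against the bicubic baseline
#'
#' Generates (or accepts) synthetic paired datasets, trains one model per
#' dataset/scale combination, and evaluates both the trained model and the
#' bicubic baseline on the held-out split, producing the standard
#' lightweight-SR report: Params[K], Runtime[ms], PSNR, SSIM per row.
#' Runtime is informational only (hardware-dependent).
#'
#' @param modalities phantom modalities to benchmark.
#' @param scales upscaling factors.
#' @param n images per dataset.
#' @param steps training steps per model.
#' @param config base [sr_config()] (its scale is overridden per row); the
#'   default benchmark profile is a compact network so the harness runs in
#'   minutes on a CPU.
#' @param opts [train_options()] used for each training run.
#' @param seed base seed for data generation and training.
#' @return data.frame of class `metric_report` with one row per
#'   (model, dataset, scale).
#' @export
run_benchmark <- function(modalities = c("ct_mri_like", "ultrasound_like"),
                          scales = c(2L, 4L), n = 8L, steps = 200L,
                          config = sr_config(feature_width = 16L,
                                             num_blocks = 3L,
                                             esa_reduction = 4L,
                                             head_width = 12L,
                                             head_width2 = 10L),
                          opts = train_options(steps = steps,
                                               batch_size = 8L,
                                               patch_size = 24L,
                                               learning_rate = 1e-3),
                          seed = 1L) {
  rows <- list()
  for (mod in modalities) {
    for (sc in scales) {
      ph <- phantom_spec(mod, seed = seed)
      dg <- degradation_spec(scale = sc, seed = seed)
      data <- make_dataset(n, ph, dg)
      cfg <- config
      cfg$scale <- as.integer(sc)
      cfg$seed <- as.integer(seed)
      opts$steps <- as.integer(steps)
      opts$seed <- as.integer(seed)
      model <- sr_build(cfg)
      fit <- sr_train(model, data, opts)
      ours <- evaluate(fit$model, data, split = "test", model_name = "ours")
      bic <- evaluate(bicubic_sr(sc), data, split = "test",
                      model_name = "bicubic")
      for (ev in list(ours, bic))
        rows[[length(rows) + 1L]] <- data.frame(
          scale = sc, dataset = mod, model = ev$model_name,
          params_k = ev$params_k, runtime_ms = ev$runtime_ms,
          psnr_db = ev$psnr_db, ssim = ev$ssim)
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("metric_report", "data.frame")
  report
}

#' Render a metric report as text table and CSV lines
#'
#' The text table mirrors the conventional comparison layout (Scale,
#' Model, Params \[K\], Runtime \[ms\], then a fused "PSNR/SSIM" cell per
#' dataset, PSNR to 2 decimals and SSIM to 4); the CSV keeps separate,
#' numerically exact columns.
#'
#' @param report a `metric_report` (non-empty).
#' @return list with `text` (character vector of table lines) and `csv`
#'   (character vector of CSV lines).
#' @export
render_report <- function(report) {
  if (is.null(report) || nrow(report) == 0)
    stop("empty report", call. = FALSE)
  datasets <- unique(report$dataset)
  key <- unique(report[, c("scale", "model", "params_k")])
  hdr <- c("Scale", "Model", "Params [K]", "Runtime [ms]",
           paste0(datasets, " PSNR/SSIM"))
  body <- lapply(seq_len(nrow(key)), function(i) {
    sub <- report[report$scale == key$scale[i] & report$model == key$model[i], ]
    cells <- vapply(datasets, function(d) {
      r <- sub[sub$dataset == d, ]
      if (nrow(r) == 0) "-" else sprintf("%.2f/%.4f", r$psnr_db[1], r$ssim[1])
    }, character(1))
    c(sprintf("%dx", key$scale[i]), key$model[i],
      as.character(key$params_k[i]),
      sprintf("%.2f", mean(sub$runtime_ms)), cells)
  })
  tab <- rbind(hdr, do.call(rbind, body))
  widths <- apply(nchar(tab), 2, max)
  text <- apply(tab, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
  con <- textConnection("csv_out", "w", local = TRUE)
  utils::write.csv(as.data.frame(report), con, row.names = FALSE)
  close(con)
  list(text = unname(text), csv = csv_out)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(render_report(x)$text, sep = "\n")
  invisible(x)
}
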