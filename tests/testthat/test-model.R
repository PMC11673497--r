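test_that("forward maps HxWx1 to exactly scale-times larger outputs", {
  cases <- list(list(scale = 2L, h = 24L, w = 24L),
                list(scale = 2L, h = 17L, w = 13L), # odd dims
                list(scale = 4L, h = 16L, w = 16L),
                list(scale = 4L, h = 11L, w = 9L))
  for (cs in cases) {
    model <- sr_build(tiny_config(scale = cs$scale))
    y <- predict(model, rand_image(cs$h, cs$w))
    expect_equal(dim(y), c(cs$scale * cs$h, cs$scale * cs$w))
    expect_true(all(is.finite(y)))
  }
})

test_that("identical seed and config give identical weights and outputs", {
  m1 <- sr_build(tiny_config())
  m2 <- sr_build(tiny_config())
  expect_identical(m1$params, m2$params)
  x <- rand_image(16, 16, seed = 3)
  expect_identical(predict(m1, x), predict(m2, x))
  m3 <- sr_build(tiny_config(seed = 99L))
  expect_false(identical(m1$params, m3$params))
})

test_that("a zero-weight residual block is the identity map", {
  model <- zero_model(tiny_config())
  set.seed(21)
  z <- array(rnorm(12 * 10 * 8 * 2), c(12, 10, 8, 2))
  bf <- medsr:::block_fwd(model, 1L, z, training = FALSE, model$buffers)
  expect_equal(bf$y, z, tolerance = 1e-14)
  # hence the whole trunk equals the shallow features: with zero weights
  # everywhere the network output is exactly zero
  y <- predict(model, rand_image(12, 12, seed = 4))
  expect_equal(y, matrix(0, 24, 24))
})

test_that("the attention gate is a sigmoid map in (0,1) broadcast over channels", {
  model <- sr_build(tiny_config())
  set.seed(22)
  x <- array(rnorm(17 * 13 * 8 * 1), c(17, 13, 8, 1))
  ef <- medsr:::esa_fwd(model$params, "b1.", x, training = FALSE)
  expect_equal(dim(ef$y), dim(x)) # odd dims restored exactly
  a <- ef$cache$a
  expect_true(all(a > 0 & a < 1))
  expect_equal(dim(a)[3], 1L) # single-channel map
  # zero-weight ESA halves its input: sigmoid(0) = 0.5
  zm <- zero_model(tiny_config())
  ef0 <- medsr:::esa_fwd(zm$params, "b1.", x, training = FALSE)
  expect_equal(ef0$y, 0.5 * x, tolerance = 1e-14)
})

test_that("whole-network backward agrees with finite differences", {
  cfg <- sr_config(scale = 2L, feature_width = 4L, num_blocks = 1L,
                   esa_reduction = 4L, head_width = 4L, seed = 5L)
  model <- sr_build(cfg)
  set.seed(23)
  x <- array(runif(8 * 8), c(8, 8, 1, 1))
  t <- array(runif(16 * 16), c(16, 16, 1, 1))
  loss_of <- function(m) {
    y <- medsr:::model_fwd(m, x, training = TRUE)$y
    mean((y - t)^2)
  }
  out <- medsr:::model_fwd(model, x, training = TRUE)
  gy <- 2 * (out$y - t) / length(t)
  bw <- medsr:::model_bwd(model, out$cache, gy)
  # check a representative subset of parameter tensors end-to-end
  for (nm in c("shallow", "b1.c1", "b1.c4", "b1.bn2", "b1.esa.c2",
               "b1.esa.c4", "head.u1", "head.out")) {
    for (part in names(model$params[[nm]])) {
      fd <- numeric_grad(function(v) {
        m2 <- model
        d <- dim(model$params[[nm]][[part]])
        m2$params[[nm]][[part]] <- array(v, if (is.null(d)) length(v) else d)
        loss_of(m2)
      }, model$params[[nm]][[part]], eps = 1e-6)
      expect_equal(as.numeric(bw$grads[[nm]][[part]]), as.numeric(fd),
                   tolerance = 1e-4,
                   label = paste("analytic grad", nm, part))
    }
  }
  # and the input gradient
  fd_x <- numeric_grad(function(v) {
    y <- medsr:::model_fwd(model, array(v, dim(x)), training = TRUE)$y
    mean((y - t)^2)
  }, x, eps = 1e-6)
  expect_equal(as.numeric(bw$gx), as.numeric(fd_x), tolerance = 1e-4)
})

test_that("parameter count equals the closed-form sum over the layer list", {
  for (cfg in list(tiny_config(), tiny_config(scale = 4L),
                   sr_config(scale = 2L, feature_width = 16L, num_blocks = 2L,
                             esa_reduction = 8L, head_width = 7L),
                   sr_config(scale = 2L, feature_width = 8L, num_blocks = 1L,
                             use_bn_branch = FALSE))) {
    model <- sr_build(cfg)
    # independent arithmetic over the recorded layer list
    want <- sum(vapply(seq_len(nrow(model$layers)), function(i) {
      l <- model$layers[i, ]
      if (l$kind == "conv") l$kernel^2 * l$cin * l$cout + l$cout else 2 * l$cin
    }, numeric(1)))
    expect_equal(count_parameters(model), want)
  }
  # hand-checked micro example: conv3x3 1->8 has 80 parameters
  expect_equal(3^2 * 1 * 8 + 8, 80)
})

test_that("width calibration hits the printed parameter budgets", {
  cfg2 <- calibrate_width(452, 2L)
  m2 <- sr_build(cfg2)
  expect_equal(round(count_parameters(m2) / 1000), 452)
  cfg4 <- calibrate_width(468, 4L, trunk = cfg2)
  m4 <- sr_build(cfg4)
  expect_equal(round(count_parameters(m4) / 1000), 468)
  # trunks are shared: same width/depth/attention and first head stage
  expect_equal(cfg4$feature_width, cfg2$feature_width)
  expect_equal(cfg4$num_blocks, cfg2$num_blocks)
  expect_equal(cfg4$esa_reduction, cfg2$esa_reduction)
  expect_equal(cfg4$head_width, cfg2$head_width)
  # trunk parameter tensors have identical shapes
  trunk_names <- grep("^head", names(m2$params), invert = TRUE, value = TRUE)
  expect_identical(lapply(m2$params[trunk_names], function(p) lapply(p, dim)),
                   lapply(m4$params[trunk_names], function(p) lapply(p, dim)))
  # defaults mirror the calibrated configuration
  expect_equal(cfg2$feature_width, sr_config()$feature_width)
  expect_equal(cfg2$head_width, sr_config()$head_width)
})

test_that("invalid configurations are rejected", {
  expect_error(sr_config(scale = 3), "scale")
  expect_error(sr_config(feature_width = 10, esa_reduction = 4),
               "esa_reduction")
  expect_error(sr_config(num_blocks = 0), "num_blocks")
  expect_error(calibrate_width(1, 2L), "calibration error")
  expect_error(medsr:::model_fwd(sr_build(tiny_config()),
                                 array(0, c(8, 8, 2, 1))), "channel")
})

test_that("model configurations round-trip through yaml and json files", {
  cfg <- tiny_config(scale = 4L)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_sr_config(cfg, path)
    expect_equal(load_sr_config(path), cfg)
  }
  expect_error(save_sr_config(cfg, "x.toml"), "yaml")
})
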