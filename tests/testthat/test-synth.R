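test_that("phantoms are deterministic, in range, and default-sized per modality", {
  s1 <- phantom_spec("ct_mri_like", size = 128L, seed = 42L)
  p1 <- make_phantom(s1)
  p2 <- make_phantom(s1)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_gt(stats::sd(p1), 0.05) # has actual structure, not flat
  expect_equal(dim(make_phantom(phantom_spec("ct_mri_like", size = 64L))),
               c(64L, 64L))
  expect_equal(phantom_spec("ct_mri_like")$size, 512L)
  expect_equal(phantom_spec("ultrasound_like")$size, 256L)
  u1 <- make_phantom(phantom_spec("ultrasound_like", size = 128L, seed = 3L))
  expect_true(all(u1 >= 0 & u1 <= 1))
  u2 <- make_phantom(phantom_spec("ultrasound_like", size = 128L, seed = 4L))
  expect_false(identical(u1, u2)) # different seeds differ
  expect_error(phantom_spec("ct_mri_like", size = 126L), "divisible")
  expect_error(phantom_spec("ct_mri_like", size = 32L), ">= 64")
})

test_that("degradation produces exact LR sizes and respects its switches", {
  hr <- make_phantom(phantom_spec("ct_mri_like", size = 128L, seed = 5L))
  for (sc in c(2L, 4L)) {
    lr <- degrade(hr, degradation_spec(scale = sc))
    expect_equal(dim(lr), dim(hr) %/% sc)
    expect_true(all(lr >= 0 & lr <= 1))
  }
  # constants pass through blur + bicubic exactly (normalised kernels)
  cst <- matrix(0.5, 64, 64)
  lr <- degrade(cst, degradation_spec(scale = 2L, blur_sigma = 1))
  expect_equal(lr, matrix(0.5, 32, 32), tolerance = 1e-12)
  # noise is seeded and reproducible
  d1 <- degrade(hr, degradation_spec(scale = 2L, noise_sigma = 0.05, seed = 9L))
  d2 <- degrade(hr, degradation_spec(scale = 2L, noise_sigma = 0.05, seed = 9L))
  expect_identical(d1, d2)
  d3 <- degrade(hr, degradation_spec(scale = 2L, noise_sigma = 0.05, seed = 10L))
  expect_false(identical(d1, d3))
  expect_error(degrade(hr[1:127, ], degradation_spec(scale = 2L)), "divisible")
})

test_that("noise statistics match the specification", {
  # mean(LR_noisy - LR_clean) ~ 0 and sd ~ noise_sigma over >= 1e4 pixels
  hr <- make_phantom(phantom_spec("ct_mri_like", size = 256L, seed = 6L))
  hr <- 0.25 + 0.5 * hr # keep away from clipping bounds
  sig <- 0.02
  clean <- degrade(hr, degradation_spec(scale = 2L, noise_sigma = 0))
  noisy <- degrade(hr, degradation_spec(scale = 2L, noise_sigma = sig,
                                        seed = 11L))
  diff <- noisy - clean
  n <- length(diff)
  expect_gte(n, 1e4)
  se_mean <- sig / sqrt(n)
  expect_lt(abs(mean(diff)), 3 * se_mean)
  se_sd <- sig / sqrt(2 * (n - 1))
  expect_lt(abs(stats::sd(diff) - sig), 3 * se_sd)
})

test_that("bicubic upscaling meets its baseline contracts", {
  lr <- rand_image(32, 32, seed = 7)
  expect_equal(dim(bicubic_upscale(lr, 2L)), c(64L, 64L))
  expect_equal(dim(bicubic_upscale(lr, 4L)), c(128L, 128L))
  expect_equal(bicubic_upscale(matrix(0.3, 16, 16), 2L), matrix(0.3, 32, 32),
               tolerance = 1e-12)
  # round-trip sanity: degrade then bicubic-upscale stays above 10 dB
  hr <- make_phantom(phantom_spec("ct_mri_like", size = 128L, seed = 8L))
  lr2 <- degrade(hr, degradation_spec(scale = 2L))
  expect_gt(psnr(bicubic_upscale(lr2, 2L), hr), 10)
})

test_that("datasets pair LR/HR correctly, split deterministically, and regenerate", {
  ph <- phantom_spec("ct_mri_like", size = 64L, seed = 20L)
  dg <- degradation_spec(scale = 2L, seed = 20L)
  d <- make_dataset(10L, ph, dg)
  expect_length(d$pairs, 10L)
  for (p in d$pairs) expect_equal(dim(p$lr), dim(p$hr) %/% 2L)
  expect_equal(as.numeric(table(factor(d$split, c("train", "val", "test")))),
               c(8, 1, 1))
  expect_equal(sum(table(d$split)), 10)
  d2 <- make_dataset(10L, ph, dg)
  expect_identical(d, d2)
  # pair i is the phantom with seed base+i-1
  expect_identical(d$pairs[[3]]$hr,
                   make_phantom(phantom_spec("ct_mri_like", size = 64L,
                                             seed = 22L)))
  expect_error(make_dataset(0L, ph, dg), "n must be")
})
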