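---
title: "medsr: model, data generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medsr: model, data generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsr)
```

## The problem

Single-image super-resolution (SISR) reconstructs a high-resolution (HR)
image from one low-resolution (LR) observation. In medical imaging the
LR image is typically single-channel (CT, MRI, ultrasound), and the
clinically relevant content — organ boundaries, small lesions,
calcifications — lives in exactly the high-frequency detail that the
acquisition lost. `medsr` implements a lightweight residual
convolutional network for this setting, together with everything needed
to exercise it without patient data: a seeded phantom generator, the
HR→LR degradation pipeline, paired-patch augmentation, MSE training,
and reference PSNR/SSIM metrics.

## The network

The macro-architecture is a residual-feature trunk with a sub-pixel
upsampling head:

```
input (H x W x 1)
  -> conv3x3 (1 -> C)                    "shallow features" s
  -> B residual blocks (C -> C)
  -> conv3x3 (C -> C), + s               long skip
  -> conv3x3 (C -> 4m), pixel-shuffle x2 [-> conv3x3 (m -> 4m2), shuffle x2]
  -> conv3x3 (-> 1)                      output (rH x rW x 1)
```

Each residual block runs, in order:

1. a 1x1 convolution (`C -> C`) producing the block's working features;
2. two parallel 3x3 branches on it — one with batch normalisation, one
   without — each followed by ReLU;
3. channel concatenation of the two branches and a 1x1 fusion back to
   `C`;
4. the same dual-branch + concatenation + fusion structure a second
   time, with the second fusion preceded by *size-preserving* max
   pooling (kernel 3, stride 1, padding 1);
5. an enhanced spatial attention (ESA) gate;
6. a residual skip: the block input is added to the gated output.

Three choices here were genuinely open and deserve justification:

* **Residual skip.** The dual-branch/concatenation stack on its own is
  not residual; calling the unit a residual block only makes sense with
  a block-input skip, and the skip is what makes the zero-weight
  configuration an exact identity (a property the tests pin down). We
  add the skip after the attention gate.
* **Size-preserving pooling.** Stride-2 max pooling inside an SR trunk
  would destroy the resolution the network exists to recover. We keep
  the pooling's feature-selection role but make it size-preserving
  (3x3, stride 1, padding 1), exposed as `pool_kernel`.
* **1x1 vs 3x3 entry conv.** The block-entry convolution is 1x1 (a
  channel mixer); the network-level shallow feature extractor is 3x3.

### Enhanced spatial attention

The ESA gate computes a per-pixel attention map in (0,1) and multiplies
the features by it. Internals: a 1x1 squeeze to `C/esa_reduction`
channels, a stride-2 3x3 convolution followed by 7/3 max pooling for
spatial context, a 3x3 + ReLU refinement, bilinear upsampling back to
the input size, addition of a 1x1 skip of the squeezed input, a final
1x1 projection to a **single channel**, and a sigmoid. The map is
broadcast across channels; a per-channel map would also be defensible,
but a single-channel gate matches the "spatial" in the name, costs
fewer parameters, and keeps the gate interpretable as a saliency map.
With all-zero weights the gate outputs sigmoid(0) = 0.5 everywhere —
the tests use this as a closed-form anchor. Pool windows are clamped to
the map size so the gate works on arbitrarily small patches; the
bilinear resampling is built from explicit weight matrices so its exact
adjoint is available to backpropagation.

### Width calibration and the parameter budgets

The lightweight design point this package targets is 452K trainable
parameters at 2x and 468K at 4x, with the two models sharing a trunk
and differing only in the upsampling head. Those two constraints
interact awkwardly with width granularity: their 16K difference pins
the head width if the 4x head reuses it verbatim, and no trunk width
then lands inside the 452K rounding window. We therefore give the 4x
head's second pixel-shuffle stage its own width `head_width2`, keep the
depth fixed at `B = 6`, require the head to be no wider than the trunk,
and let `calibrate_width()` search the attention squeeze divisor
(4, 8, 2), the trunk width (ascending multiples of the divisor) and the
head widths in a documented ascending order. The first solution —
`C = 40`, `esa_reduction = 8`, `head_width = 25`, `head_width2 = 18`,
i.e. 451,612 and 467,821 parameters — is the package default
(`sr_config()`), and `count_parameters()` on the built models is what
the acceptance script reports.

### Initialisation, loss, optimiser

Convolutions use Kaiming-uniform fan-in initialisation
(`bound = sqrt(6 / (k^2 * c_in))`), biases zero, batch norm at scale 1
/ shift 0, all drawn from `config$seed`, so identical seeds give
bitwise-identical weights. Training minimises the mean squared error on
normalised `[0, 1]` intensities — stable gradients regardless of the
source bit depth — with Adam (0.9, 0.999) and a step-decay schedule.
The training loop samples aligned LR/HR patch pairs uniformly from the
training images; batch norm uses biased batch statistics with running
averages (momentum 0.1) for evaluation.

## The synthetic data generator

The generator emulates two archetypes of clinical SR datasets without
redistributing any real data: `ct_mri_like` phantoms (512x512 by
default) are piecewise-smooth — a skull-like enclosing ellipse, random
interior ellipses with distinct intensities, a mild polynomial bias
field, and slight smoothing so edges are band-limited rather than
ideal; `ultrasound_like` phantoms (256x256) are a smoothed random
anatomy field with a hypoechoic region, bright ellipsoidal inclusions,
multiplicative unit-mean speckle of configurable strength, and gentle
depth attenuation. Everything is drawn from the generator's seed, so datasets
regenerate bit-exactly.

What the phantoms deliberately do **not** model: scanner-specific noise
spectra, partial-volume effects, anisotropic resolution, pathology
diversity, or annotation structure. Passing tests on phantoms therefore
demonstrates that the implementation learns and evaluates correctly on
piecewise-smooth, speckled single-channel content — not that the
trained weights transfer to clinical images.

The degradation pipeline is Gaussian blur (optional) → bicubic
downsampling → additive Gaussian noise (optional, seeded) → clipping.
Clinical LR images may come from native low-resolution acquisition
rather than from any downsampling of an HR image; since that forward
process is unobservable, we model it explicitly with bicubic
downsampling — the field's default assumption — and expose blur/noise
switches to emulate harsher acquisition. The bicubic kernel is the
Keys `a = -1/2` cubic with half-pixel-centred coordinates; when
minifying, the kernel is widened by the scale factor (anti-aliasing,
the `imresize` convention) and every output row of the resampling
matrix is normalised to sum to one, so constants — and, in the
interior, linear ramps — are reproduced exactly.

## Metrics

PSNR is `10 * log10(max_i^2 / MSE)`; the widely reprinted
`20 * log10(MAX/sqrt(MSE))` form is the same quantity. Identical images
report `Inf`. SSIM follows the standard windowed form with `k1 = 0.01`,
`k2 = 0.03` and an 11x11 Gaussian window (sigma 1.5) by default;
windows are valid-mode (fully inside the image, no padding), variances
are the biased ML estimates, and the mean of the per-window map is
returned. These conventions match the reference implementation in
scikit-image (`gaussian_weights = TRUE, use_sample_covariance = FALSE`)
to near machine precision; the package's own tests check against a
brute-force window-loop oracle instead, so the suite is self-contained.

## Augmentation

Geometric augmentation is restricted to quarter-turn rotations and
flips: these are exact permutations, so the LR/HR pair stays perfectly
aligned and — because the degradation kernel is separable and symmetric
— degradation commutes with augmentation, a property the suite asserts
numerically. Photometric jitter (brightness shift, contrast scaling) is
anchored at the HR mean and applied with identical draws to both images
of a pair. Noise/blur jitter defaults to the LR image only (simulating
a low-quality acquisition of the same anatomy); a flag applies it to
both. Class-balancing by over/undersampling, which appears in the
original preprocessing narrative, has no analogue in an SR task without
labels and is deliberately out of scope.

## Problem sizes used in the tests and benchmark

All suite and benchmark sizes are package choices, made once, to keep a
full run comfortable on a single CPU:

* Structural and gradient tests run tiny models (width 4–8, one block)
  on 8x8 to 17x13 inputs; gradients are checked against central finite
  differences end-to-end.
* The learning-sanity experiment trains a compact profile (width 8, one
  block, attention squeeze 4, head width 8) on 20 default-size
  `ct_mri_like` phantoms with clean 2x bicubic degradation — 16
  train / 2 val / 2 test — for 1000 Adam steps, batch 16, LR patches
  32x32, constant learning rate 1e-2 with `beta2 = 0.99`. These are
  pilot-run choices made once: early learning-rate decay stalls
  convergence well short of the baseline, and Adam's default
  `beta2 = 0.999` adapts its second moments too slowly for a
  1000-step budget (0.99 is worth over 2 dB here). The compact width
  is an optimisation-speed choice, not a capacity limit — a linear
  least-squares probe shows the clean-2x task is solvable more than
  2 dB above bicubic. The trained model must beat bicubic's held-out
  mean PSNR by at least 0.3 dB.
* The default benchmark profile (`run_benchmark()`) uses width 16 /
  three blocks over 8 images per modality and 200 steps — it exists to
  exercise the full report pipeline, not to reach the quality plateau.

Scaling any of these up (the calibrated 452K-parameter model, thousands
of steps, more phantoms) is a matter of configuration, and the same
code paths run unchanged.

## Degenerate inputs and numerical edges

* Odd image sizes propagate exactly: pixel shuffle guarantees `r`-times
  output dims, and the ESA gate's downsample/upsample restores odd
  sizes through explicit target-size resampling.
* Pool windows clamp to the available extent, so attention works down
  to 1x1 internal maps.
* Max pooling uses implicit `-Inf` padding (zero padding would corrupt
  negative feature maps); ties take the first maximum in column order,
  and the backward pass routes gradients to the recorded argmax.
* Batch norm uses `eps = 1e-5`; an all-zero branch normalises to zero
  rather than NaN.
* PSNR of identical images is `Inf` by contract; training aborts with a
  diagnostic on a non-finite loss instead of continuing silently.
* Checkpoints embed config, weights and buffers; save → load → evaluate
  reproduces metrics bit-for-bit.

## Known limitations

* CPU-only; throughput is roughly 0.1–0.6 s per optimisation step at
  the compact profiles above, so reaching the quality plateau of the
  full 452K model requires patience (or a faster BLAS).
* The BN-branch behaviour under very small batches inherits the usual
  batch-norm caveats; `use_bn_branch = FALSE` is available for
  ablation.
* The phantom generator targets statistical structure, not anatomical
  realism; results on it bound implementation correctness, not
  clinical performance.
* Only single-channel input paths are implemented; RGB and
  deconvolution-based upsampling are out of scope.
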