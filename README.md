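# fdacnn

De-aliasing of sparsely sampled magnetic resonance images with a fully
dense attention convolutional neural network (FDA-CNN), implemented as a
self-contained R package: k-space model, under-sampling mask generators,
zero-filled reconstruction, the network and its plain Unet baseline,
MSE/Adam training, and a four-metric evaluation harness (SSIM, PSNR,
NRMSE, pixel-domain VIF). A seeded brain-like phantom generator supplies
paired ground-truth images and k-space, so the whole pipeline runs at
desk scale on one CPU with no external datasets.

## Who this is for

Researchers and students working on accelerated MRI reconstruction who
want an inspectable, dependency-light reference implementation of
dense-block/attention-gate de-aliasing — every layer, mask rule and
metric is plain R (with small compiled convolution kernels), not a
framework call.

## The model

Acquisition is modelled retrospectively: a fully sampled k-space
`y = F T` (centered, orthonormal 2D DFT of the artifact-free image `T`)
is element-wise masked, `y_hat = U ⊙ y`, and the zero-filled magnitude
image `x_hat = |F⁻¹ y_hat|` — aliased and blurred at 20% sampling
(acceleration factor 5) — is mapped back to the clean image by a trained
network: `R = NN(x_hat)`, minimizing the mean squared error
`L = (1/N) Σ (T_i − R_i)²` with Adam (β₁ = 0.9, β₂ = 0.999, learning
rate 1e-4 decaying ×0.95 every 20 epochs, batch size 8).

The FDA-CNN is a five-level encoder/decoder. Each level holds a dense
block (four layers; layer ℓ gets the concatenation of the block input
and all previous outputs, compresses with a 1×1 convolution and emits
`k_m` new maps with a 3×3 convolution); growth rate and width double per
level from `k₁ = 8`, `f₁ = 64` over a 32-channel stem. The decoder adds
an attention gate on every skip connection: coefficients in (0, 1)
computed from the skip features and the deeper decoder signal multiply
the skip before concatenation. In total: 9 dense blocks and 97
convolutional + transposed-convolutional layers (the Unet baseline has
23).

Three Cartesian masks are provided: 2D Gaussian points, 1D Gaussian
lines, and the mixed center-periphery line mask (MCP-US) that keeps 50%
of its budget as a contiguous central low-frequency block, 25% at the
outermost edges and 25% drawn at random from the band between.

## Worked example

```r
library(fdacnn)

# 250 phantoms at 64x64: 200 train / 30 val / 20 test
ds   <- generate_dataset(250, phantom_spec(64, seed = 1),
                         split_counts = c(200, 30, 20))
mspec <- mask_spec("mcp", sampling_rate = 0.2, image_size = 64, seed = 1)
make_mask(mspec)$counts
#>   S s_c s_p s_r
#>  13   6   3   4      # 13 of 64 lines kept: 6 center, 3 edge, 4 random

# quarter-width FDA-CNN (same 97-layer topology), 30 epochs
cfg <- model_config(k_1 = 2, f_1 = 16, stem_channels = 8, input_size = 64)
fit <- train(build_model(cfg, seed = 1), ds, mspec,
             train_config(epochs = 30, seed = 1))

te   <- which(ds$split == "test")
mask <- fit$mask
zf   <- lapply(te, function(i) zero_filled_recon(ds$kspaces[[i]], mask))
rec  <- lapply(te, function(i)
  reconstruct(fit$best_model, apply_mask(ds$kspaces[[i]], mask), mask))
evaluate_batch(ds$images[te], zf)$means["psnr"]   # zero filling: 20.27 dB
evaluate_batch(ds$images[te], rec)$means["psnr"]  # trained net:  27.08 dB
```

The ~6.8 dB PSNR gain (with SSIM rising from 0.63 to 0.81) is the
de-aliasing effect this package exists to exhibit: the trained network
removes ghosting that zero filling leaves in. Architecture audits are
one-liners:

```r
count_layers(build_model(model_config(input_size = 64), seed = NULL))  # 97
count_layers(build_unet_baseline(model_config(input_size = 64), seed = NULL))  # 23
dense_block_plan(5, model_config())  # k_m = 128 on a 512-channel block input
```

A command-line front end wrapping the same functions lives at
`inst/cli/fdacnn.R` (`phantom`, `mask`, `subsample`, `model`, `run`
subcommands), and `run_end_to_end()` drives the whole pipeline from a
YAML manifest.

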