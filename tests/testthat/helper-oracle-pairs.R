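# Deterministic (target, distorted) image pairs used for metric
# cross-checks: phantoms degraded by noise, blur, intensity scaling and
# zero-filled undersampling, covering the distortion types the metrics are
# meant to rank.
make_oracle_pairs <- function(n = 50L) {
  spec <- phantom_spec(64, n_ellipses = 6, noise_sd = 0, seed = 99)
  blur <- function(img, sd) fdacnn:::gaussian_blur_fft(img, sd)
  masks <- list(
    make_mask(mask_spec("mcp", 0.2, 64, seed = 11)),
    make_mask(mask_spec("1dg", 0.3, 64, seed = 12)),
    make_mask(mask_spec("2dg", 0.25, 64, seed = 13)))
  lapply(seq_len(n), function(i) {
    tgt <- generate_phantom(spec, i - 1L)
    r <- fdacnn:::with_seed(1000L + i, {
      switch((i %% 5L) + 1L,
        pmin(pmax(tgt + matrix(stats::rnorm(64 * 64, sd = 0.05), 64), 0), 1),
        blur(tgt, 1 + (i %% 3)),
        zero_filled_recon(forward_fft(tgt), masks[[(i %% 3L) + 1L]]),
        pmin(pmax(0.85 * tgt + 0.05 +
                    matrix(stats::rnorm(64 * 64, sd = 0.02), 64), 0), 1),
        pmin(pmax(blur(tgt, 1.5) +
                    matrix(stats::rnorm(64 * 64, sd = 0.03), 64), 0), 1))
    })
    list(target = tgt, recon = r)
  })
}
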