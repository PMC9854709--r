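test_that("PSNR follows the 8-bit peak-signal convention", {
  t255 <- matrix(255, 8, 8); r254 <- matrix(254, 8, 8)
  expect_equal(psnr(t255, r254, data_max = 255), 20 * log10(255),
               tolerance = 1e-10)
  # halving the MSE adds exactly 10*log10(2) dB
  a <- matrix(0, 8, 8)
  b1 <- matrix(c(rep(0.2, 32), rep(0, 32)), 8)
  b2 <- matrix(c(rep(0.2, 16), rep(0, 48)), 8)
  expect_equal(psnr(a, b2) - psnr(a, b1), 10 * log10(2), tolerance = 1e-10)
  # identical pair returns the cap sentinel
  expect_equal(psnr(t255, t255, cap = 100), 100)
  expect_true(is.infinite(psnr(t255, t255)))
  expect_error(psnr(t255, matrix(0, 4, 16)), "shape")
})

test_that("SSIM identities and structure sensitivity", {
  img <- generate_phantom(phantom_spec(64, seed = 1), 0)
  expect_equal(ssim(img, img), 1, tolerance = 1e-12)
  # structural inversion degrades similarity
  bin <- matrix(rep(c(0, 1), length.out = 64 * 64), 64)
  expect_lt(ssim(bin, 1 - bin), 1)
  # constant reference only defined when identical
  cst <- matrix(0.5, 64, 64)
  expect_equal(ssim(cst, cst), 1)
  expect_error(ssim(cst, img), "dynamic range")
})

test_that("NRMSE is range-normalized and scale-invariant", {
  img <- generate_phantom(phantom_spec(64, seed = 2), 0)
  expect_equal(nrmse(img, img), 0)
  expect_equal(nrmse(matrix(c(0, 1), 1), matrix(c(1, 0), 1)), 1)
  noisy <- img + 0.05
  expect_equal(nrmse(img, noisy), nrmse(2 * img, 2 * noisy), tolerance = 1e-12)
  expect_error(nrmse(matrix(1, 4, 4), matrix(0, 4, 4)), "dynamic range")
})

test_that("VIFP identities and monotonic degradation under blur", {
  img <- generate_phantom(phantom_spec(64, seed = 3), 0)
  expect_equal(vifp(img, img), 1, tolerance = 1e-8)
  mild <- fdacnn:::gaussian_blur_fft(img, 1)
  heavy <- fdacnn:::gaussian_blur_fft(img, 4)
  expect_lt(vifp(img, heavy), vifp(img, mild))
  expect_error(vifp(img[1:16, 1:16], img[1:16, 1:16]), "32x32")
  expect_error(vifp(matrix(1, 64, 64), img), "constant")
})

test_that("SSIM and VIFP agree with independent reference implementations", {
  pairs <- make_oracle_pairs(50)
  my_ssim <- vapply(pairs, function(p) ssim(p$target, p$recon), 0)
  my_vifp <- vapply(pairs, function(p) vifp(p$target, p$recon), 0)
  expect_lt(max(abs(my_ssim - oracle_reference$ssim)), 1e-3)
  expect_lt(max(abs(my_vifp - oracle_reference$vifp)), 1e-3)
})

test_that("PSNR and NRMSE are consistent transforms of the same error", {
  img <- generate_phantom(phantom_spec(64, seed = 4), 0)
  set.seed(1)
  for (sd in c(0.01, 0.05, 0.1)) {
    noisy <- img + matrix(rnorm(64 * 64, sd = sd), 64)
    # NRMSE * range * 255 = 255-scale RMSE = 255 * 10^(-PSNR/20) * ... :
    rmse8 <- 255 * nrmse(img, noisy) * (max(img) - min(img))
    expect_equal(10 * log10(255^2 / rmse8^2), psnr(img, noisy),
                 tolerance = 1e-10)
  }
})

test_that("batch evaluation aggregates per-image metrics", {
  imgs <- lapply(0:2, function(i) generate_phantom(phantom_spec(64, seed = 6), i))
  recs <- lapply(imgs, function(im)
    pmin(pmax(im + matrix(rnorm(64 * 64, sd = 0.03), 64), 0), 1))
  rep1 <- evaluate_batch(imgs, recs)
  expect_equal(nrow(rep1$per_image), 3)
  expect_equal(unname(rep1$means["ssim"]), mean(rep1$per_image$ssim))
  # identical pair: perfect scores with the PSNR sentinel
  rep2 <- evaluate_batch(imgs[1], imgs[1])
  expect_equal(rep2$per_image$ssim, 1)
  expect_equal(rep2$per_image$nrmse, 0)
  expect_equal(rep2$per_image$vifp, 1, tolerance = 1e-8)
  expect_equal(rep2$per_image$psnr, 100)
  # permutation stability
  rep3 <- evaluate_batch(imgs[3:1], recs[3:1])
  expect_equal(sort(rep3$per_image$ssim), sort(rep1$per_image$ssim))
  expect_equal(unname(rep3$means), unname(rep1$means))
  expect_error(evaluate_batch(imgs, recs[1:2]), "length")
  # report files
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_report(rep1, csv, js)
  expect_equal(nrow(utils::read.csv(csv)), 3)
  expect_equal(jsonlite::read_json(js)$ssim, unname(rep1$means["ssim"]),
               tolerance = 1e-12)
  unlink(c(csv, js))
})
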