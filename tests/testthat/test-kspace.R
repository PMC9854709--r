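test_that("centered FFT pair is unitary and round-trips", {
  set.seed(1)
  x <- matrix(runif(64 * 64), 64)
  k <- forward_fft(x)
  expect_lt(max(abs(inverse_fft(k) - x)), 1e-10)
  # Parseval under orthonormal scaling
  expect_lt(abs(sum(x^2) - sum(Mod(k)^2)) / sum(x^2), 1e-6)
  # constant image concentrates all energy at the centered DC sample
  kc <- forward_fft(matrix(3, 32, 32))
  expect_equal(Mod(kc[17, 17]), 3 * 32, tolerance = 1e-12)
  expect_lt(max(Mod(kc[-((17 - 1) * 32 + 17)])), 1e-10)
  # DC impulse inverts to a constant magnitude image
  k1 <- matrix(0 + 0i, 32, 32); k1[17, 17] <- 32
  img <- inverse_fft(k1)
  expect_lt(diff(range(img)), 1e-12)
  expect_equal(img[1, 1], 1, tolerance = 1e-12)
  # zeros map to zeros
  expect_equal(max(inverse_fft(matrix(0 + 0i, 32, 32))), 0)
  expect_error(forward_fft(matrix(c(NA, runif(35 * 36 - 1)), 35)), "finite")
})

test_that("MCP mask composition matches the 50/25/25 center/periphery/random split", {
  m <- make_mask(mask_spec("mcp", 0.2, 100, seed = 1))
  expect_equal(unname(m$counts), c(20, 10, 5, 5))
  expect_equal(unname(m$counts["S"]),
               unname(m$counts["s_c"] + m$counts["s_p"] + m$counts["s_r"]))
  expect_equal(unname(m$counts["s_c"] / m$counts["S"]), 0.5)
  expect_equal(unname(m$counts["s_p"] / m$counts["S"]), 0.25)
  expect_equal(unname(m$counts["s_r"] / m$counts["S"]), 0.25)
  # N = 256 under the round-half-up rule
  m2 <- make_mask(mask_spec("mcp", 0.2, 256, seed = 1))
  expect_equal(unname(m2$counts), c(51, 26, 13, 12))
})

test_that("MCP center block is contiguous about DC and periphery lines sit at the edges", {
  m <- make_mask(mask_spec("mcp", 0.2, 64, seed = 3))
  N <- 64; dc <- N / 2 + 1
  lines <- m$lines
  n_c <- m$counts["s_c"]
  center <- seq(dc - floor(n_c / 2), dc + ceiling(n_c / 2) - 1)
  expect_true(all(center %in% lines))
  expect_true(dc %in% center)
  n_p <- m$counts["s_p"]
  expect_true(all(seq_len(ceiling(n_p / 2)) %in% lines))
  expect_true(all(seq(N - floor(n_p / 2) + 1, N) %in% lines))
  # random lines avoid center and periphery bands
  rnd <- setdiff(lines, c(center, seq_len(ceiling(n_p / 2)),
                          seq(N - floor(n_p / 2) + 1, N)))
  expect_length(rnd, m$counts[["s_r"]])
  expect_true(all(rnd > ceiling(n_p / 2) & rnd < N - floor(n_p / 2) + 1))
})

test_that("all mask kinds are deterministic and hit the sampling rate within one line", {
  for (kind in c("mcp", "1dg", "2dg")) {
    s <- mask_spec(kind, 0.2, 64, seed = 7)
    m1 <- make_mask(s); m2 <- make_mask(s)
    expect_identical(m1$matrix, m2$matrix)
    expect_lte(abs(mean(m1$matrix) - 0.2), 1 / 64)
    expect_true(all(m1$matrix %in% c(0, 1)))
  }
  # full sampling gives the all-ones mask for every kind
  for (kind in c("mcp", "1dg", "2dg"))
    expect_equal(min(make_mask(mask_spec(kind, 1, 64, seed = 1))$matrix), 1)
  # line masks have constant columns
  m <- make_mask(mask_spec("1dg", 0.25, 64, seed = 2))
  expect_true(all(apply(m$matrix, 2, function(col) length(unique(col)) == 1)))
  # DC line/sample always kept
  for (kind in c("mcp", "1dg", "2dg"))
    expect_equal(make_mask(mask_spec(kind, 0.2, 64, seed = 5))$matrix[33, 33], 1)
})

test_that("degenerate mask specs are rejected", {
  expect_error(make_mask(mask_spec("mcp", 0.01, 64)), "central block")
  expect_error(mask_spec("mcp", 0), "sampling_rate")
  expect_error(mask_spec("mcp", 0.2, 16), "image_size")
})

test_that("apply_mask zeroes unsampled entries and respects shapes", {
  set.seed(2)
  k <- forward_fft(matrix(runif(64 * 64), 64))
  ones <- make_mask(mask_spec("mcp", 1, 64))
  expect_equal(apply_mask(k, ones), k * 1)
  expect_equal(max(Mod(apply_mask(k, matrix(0, 64, 64)))), 0)
  m <- make_mask(mask_spec("mcp", 0.2, 64, seed = 1))
  ku <- apply_mask(k, m)
  expect_equal(sum(Mod(ku) > 0) <= m$counts[["S"]] * 64, TRUE)
  expect_equal(Mod(ku)[m$matrix == 0], rep(0, sum(m$matrix == 0)))
  expect_error(apply_mask(k[1:32, ], m), "shape")
})

test_that("zero-filled reconstruction degrades gracefully with the sampling rate", {
  img <- generate_phantom(phantom_spec(64, seed = 5), 0)
  k <- forward_fft(img)
  # full sampling is exact
  full <- zero_filled_recon(k, make_mask(mask_spec("1dg", 1, 64)))
  expect_lt(max(abs(full - img)), 1e-6)
  # more sampling, better fidelity (same kind and seed)
  lo <- zero_filled_recon(k, make_mask(mask_spec("1dg", 0.2, 64, seed = 9)))
  hi <- zero_filled_recon(k, make_mask(mask_spec("1dg", 0.5, 64, seed = 9)))
  expect_lt(psnr(img, lo), psnr(img, hi))
  # zero image reconstructs to zero
  z <- zero_filled_recon(matrix(0 + 0i, 64, 64),
                         make_mask(mask_spec("mcp", 0.2, 64, seed = 1)))
  expect_equal(max(z), 0)
})
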