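test_that("phantom generation is deterministic per (seed, index) and seed-sensitive", {
  spec <- phantom_spec(64, seed = 7)
  a <- generate_phantom(spec, 3)
  b <- generate_phantom(spec, 3)
  expect_identical(a, b)
  other <- generate_phantom(phantom_spec(64, seed = 8), 3)
  expect_gt(max(abs(a - other)), 0)
  expect_gt(max(abs(a - generate_phantom(spec, 4))), 0)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("degenerate phantom with no sub-structures is a two-level ellipse", {
  spec <- phantom_spec(64, n_ellipses = 0, noise_sd = 0, smooth_sd = 0, seed = 1)
  img <- generate_phantom(spec, 0)
  expect_equal(sort(unique(as.vector(img))), c(0, 0.85))
})

test_that("phantom spec validation rejects bad sizes and parameters", {
  expect_error(phantom_spec(60), "power of two")
  expect_error(phantom_spec(16), "power of two")
  expect_error(phantom_spec(64, noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(64, intensity_range = c(0.5, 1.5)), "intensity_range")
  expect_error(generate_phantom(phantom_spec(64), -1), "index")
})

test_that("datasets pair images with consistent k-space and honor split rules", {
  ds <- generate_dataset(10, phantom_spec(64, seed = 1))
  expect_length(ds$images, 10)
  expect_length(ds$kspaces, 10)
  for (i in seq_len(10))
    expect_lt(max(abs(inverse_fft(ds$kspaces[[i]]) - ds$images[[i]])), 1e-6)
  expect_true(all(sapply(ds$images, function(im) all(im >= 0 & im <= 1))))
  # proportional 100:30:20 rule
  expect_equal(unname(table(generate_dataset(150, phantom_spec(64))$split)),
               c(100L, 30L, 20L), ignore_attr = TRUE)
  expect_equal(unname(table(generate_dataset(3, phantom_spec(64))$split)),
               c(1L, 1L, 1L), ignore_attr = TRUE)
  expect_error(generate_dataset(2, phantom_spec(64)), "n >= 3")
  # explicit split counts
  ds2 <- generate_dataset(12, phantom_spec(64), split_counts = c(8, 2, 2))
  expect_equal(unname(table(ds2$split)), c(8L, 2L, 2L), ignore_attr = TRUE)
  expect_error(generate_dataset(12, phantom_spec(64), split_counts = c(8, 2, 1)),
               "sum to n")
  # datasets are bit-reproducible
  expect_identical(generate_dataset(5, phantom_spec(64, seed = 4))$images,
                   generate_dataset(5, phantom_spec(64, seed = 4))$images)
})

test_that("dataset text round trip preserves images and k-space", {
  dir <- file.path(tempdir(), "ds-roundtrip")
  ds <- generate_dataset(4, phantom_spec(64, seed = 2))
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$images, ds$images, tolerance = 1e-12)
  expect_lt(max(abs(back$kspaces[[1]] - ds$kspaces[[1]])), 1e-10)
  expect_equal(as.character(back$split), as.character(ds$split))
  unlink(dir, recursive = TRUE)
})

test_that("phantom volume shrinks toward the stack ends", {
  vol <- generate_volume(phantom_spec(64, noise_sd = 0, seed = 3), 11)
  content <- sapply(vol, sum)
  expect_lt(content[1], content[6])
  expect_lt(content[11], content[6])
})
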