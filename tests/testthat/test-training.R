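test_that("MSE loss matches its definition", {
  a <- matrix(runif(16), 4)
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(c(1, 2), c(0, 0)), 2.5)
  b <- matrix(runif(16), 4)
  expect_equal(mse_loss(a, b), mse_loss(b, a))
  expect_gte(mse_loss(a, b), 0)
  expect_error(mse_loss(a, matrix(0, 2, 8)), "shape")
})

test_that("learning-rate schedule decays by 0.95 every 20 epochs", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 1e-4)
  expect_equal(lr_at(19, cfg), 1e-4)
  expect_equal(lr_at(20, cfg), 9.5e-5)
  expect_equal(lr_at(40, cfg), 9.025e-5)
  expect_error(lr_at(-1, cfg), "epoch")
  # trace is non-increasing and piecewise constant with 20-epoch plateaus
  tr <- lr_at(0:100, cfg)
  expect_true(all(diff(tr) <= 0))
  expect_equal(length(unique(tr[1:20])), 1L)
  expect_equal(length(rle(tr)$lengths[1:5]), 5L)
  expect_true(all(rle(tr)$lengths[1:5] == 20))
})

test_that("training smoke run returns finite history and best weights", {
  ds <- generate_dataset(6, phantom_spec(64, seed = 3),
                         split_counts = c(4, 1, 1))
  cfg <- model_config(k_1 = 1, f_1 = 8, stem_channels = 4, input_size = 64)
  m <- build_model(cfg, seed = 1)
  tc <- train_config(epochs = 1, batch_size = 4, seed = 1)
  fit <- train(m, ds, mask_spec("mcp", 0.2, 64, seed = 1), tc)
  expect_equal(nrow(fit$history), 1)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_true(all(fit$history$train_loss >= 0))
  expect_s3_class(fit$best_model, "recon_model")
  expect_equal(fit$history$lr[1], 1e-4)
})

test_that("training is reproducible for identical seeds and configs", {
  ds <- generate_dataset(6, phantom_spec(64, seed = 3),
                         split_counts = c(4, 1, 1))
  cfg <- model_config(k_1 = 1, f_1 = 8, stem_channels = 4, input_size = 64)
  tc <- train_config(epochs = 1, batch_size = 4, seed = 9)
  f1 <- train(build_model(cfg, seed = 9), ds, mask_spec("mcp", 0.2, 64, seed = 2), tc)
  f2 <- train(build_model(cfg, seed = 9), ds, mask_spec("mcp", 0.2, 64, seed = 2), tc)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("reconstruct with a pass-through stub returns the zero-filled image", {
  ds <- generate_dataset(3, phantom_spec(64, seed = 5))
  mask <- make_mask(mask_spec("mcp", 0.2, 64, seed = 1))
  stub <- build_identity_model(64)
  ku <- apply_mask(ds$kspaces[[1]], mask)
  zf <- zero_filled_recon(ku, mask)
  expect_equal(reconstruct(stub, ku, mask), zf, tolerance = 1e-12)
  # batch form preserves count and shapes
  recs <- reconstruct(stub, lapply(ds$kspaces, apply_mask, mask = mask), mask)
  expect_length(recs, 3)
  expect_true(all(vapply(recs, function(r) all(dim(r) == c(64, 64)), TRUE)))
  expect_error(reconstruct(stub, ds$kspaces[[1]][1:32, ], mask), "shape")
})

test_that("a short training run reduces the training loss on a small task", {
  ds <- generate_dataset(20, phantom_spec(64, seed = 11),
                         split_counts = c(16, 2, 2))
  cfg <- model_config(k_1 = 1, f_1 = 8, stem_channels = 4, input_size = 64)
  tc <- train_config(epochs = 4, batch_size = 8, lr0 = 1e-3, seed = 2)
  fit <- train(build_model(cfg, seed = 2), ds, mask_spec("mcp", 0.2, 64, seed = 3), tc)
  expect_lt(fit$history$train_loss[4], fit$history$train_loss[1])
})
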