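# a narrow configuration used throughout: same topology as the default,
# quartered channel widths, small inputs
tiny_cfg <- function(size = 32, bn = TRUE)
  model_config(k_1 = 1, f_1 = 8, stem_channels = 4, input_size = size,
               batch_norm = bn)

test_that("dense block planning follows the level-doubling rule", {
  cfg <- model_config()
  p1 <- dense_block_plan(1, cfg)
  expect_equal(p1$k_m, 8)
  expect_equal(p1$f_m, 64)
  expect_equal(p1$F_in, 32) # stem width
  p2 <- dense_block_plan(2, cfg)
  expect_equal(p2$k_m, 16)
  expect_equal(p2$f_m, 128)
  expect_equal(p2$F_in, 64)
  p5 <- dense_block_plan(5, cfg)
  expect_equal(p5$k_m, 128)
  expect_equal(p5$F_in, 512)
  # concatenation identity holds at every level
  for (m in 1:5) {
    p <- dense_block_plan(m, cfg)
    expect_equal(p$f_m, p$F_in + p$L * p$k_m)
    expect_equal(p$F_in, 2^(m - 1) * cfg$stem_channels)
  }
  expect_error(dense_block_plan(6, cfg), "out of range")
  expect_error(dense_block_plan(0, cfg), "out of range")
})

test_that("a dense block contains eight convolutions with the dense recurrence", {
  spec <- dense_block_plan(1, model_config())
  frag <- build_dense_block(spec)
  expect_equal(nrow(frag), 8)
  expect_equal(sum(frag$kernel == "1x1"), 4)
  expect_equal(sum(frag$kernel == "3x3"), 4)
  # layer 4 sees the input plus three growth-rate additions: 32 + 3 * 8
  expect_equal(frag$in_ch[frag$layer == 4 & frag$kernel == "1x1"], 56)
  # every 1x1 compresses to F_in, every 3x3 emits k_m
  expect_true(all(frag$out_ch[frag$kernel == "1x1"] == spec$F_in))
  expect_true(all(frag$out_ch[frag$kernel == "3x3"] == spec$k_m))
  # block output channels: input plus four growth-rate layer outputs
  expect_equal(spec$F_in + 4 * spec$k_m, 64)
})

test_that("model configuration invariants are enforced", {
  expect_error(model_config(f_1 = 60), "f_1 = stem_channels")
  expect_error(model_config(input_size = 100), "divisible")
  expect_silent(model_config(k_1 = 2, f_1 = 16, stem_channels = 8,
                             input_size = 64))
})

test_that("FDA-CNN counts 97 conv/deconv layers and 9 dense blocks at any width", {
  m <- build_model(model_config(input_size = 64), seed = NULL)
  expect_equal(count_layers(m), 97)
  m_small <- build_model(tiny_cfg(), seed = NULL)
  expect_equal(count_layers(m_small), 97)
  n_blocks <- length(unique(sub("/dense[0-9]+\\..*$", "",
                                grep("/dense", m$inventory$where, value = TRUE))))
  expect_equal(n_blocks, 9)
  # four attention gates, three convolutions each
  expect_equal(sum(grepl("gate\\.", m$inventory$where) &
                     m$inventory$type == "conv"), 12)
  # three encoder transition convolutions
  expect_equal(sum(grepl("transition", m$inventory$where) &
                     m$inventory$type == "conv"), 3)
  expect_equal(sum(m$inventory$type == "tconv"), 4)
})

test_that("the Unet baseline counts 23 layers", {
  u <- build_unet_baseline(model_config(input_size = 64), seed = NULL)
  expect_equal(count_layers(u), 23)
})

test_that("forward passes preserve the image shape", {
  set.seed(1)
  m <- build_model(tiny_cfg(), seed = 2)
  x <- matrix(runif(32 * 32), 32)
  y <- predict(m, x)
  expect_equal(dim(y), c(32, 32))
  u <- build_unet_baseline(tiny_cfg(), seed = 2)
  expect_equal(dim(predict(u, x)), c(32, 32))
  xb <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  expect_equal(dim(predict(m, xb)), c(32, 32, 1, 3))
})

test_that("channel and spatial bookkeeping trace through the encoder", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 1)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  f <- fdacnn:::nn_forward(m, x, training = FALSE)
  dims <- lapply(f$acts, dim)
  sizes <- vapply(dims, `[`, 0L, 1)
  expect_equal(min(sizes), 32 / 2^4) # deepest level reached
  # a 32-channel-equivalent stem: first conv output has stem_channels maps
  expect_equal(dims[[2]][3], cfg$stem_channels)
  expect_equal(dim(f$out), c(32, 32, 1, 1))
})

test_that("standalone attention gate obeys range and shape contracts", {
  set.seed(3)
  x <- array(rnorm(16 * 16 * 6 * 1), c(16, 16, 6, 1))
  g <- array(rnorm(8 * 8 * 12 * 1), c(8, 8, 12, 1))
  out <- attention_gate_forward(x, g, seed = 4)
  expect_equal(dim(out$gated), dim(x))
  expect_true(all(out$alpha > 0 & out$alpha < 1))
  # saturated-open gate passes features through unchanged
  open <- attention_gate_forward(x, g, seed = 4, saturate_open = TRUE)
  expect_lt(max(abs(open$gated - x)), 1e-6)
  expect_error(attention_gate_forward(x, array(0, c(16, 16, 3, 1))), "half")
})

test_that("saturating the gate logits reproduces the gates-off network", {
  set.seed(5)
  m <- build_model(tiny_cfg(), seed = 6)
  # zero the attention-logit weights and saturate their biases; psi convs
  # are exactly the convolutions feeding a sigmoid
  for (k in seq_along(m$nodes)) {
    nd <- m$nodes[[k]]
    if (identical(nd$op, "sigmoid")) {
      conv_node <- m$nodes[[nd$inputs[1]]]
      p <- conv_node$p
      m$params[[paste0(p, ".W")]][] <- 0
      m$params[[paste0(p, ".b")]][] <- 30
    }
  }
  x <- matrix(runif(32 * 32), 32)
  y_sat <- predict(m, x)
  y_off <- predict(m, x, gates_off = TRUE)
  expect_lt(max(abs(y_sat - y_off)), 1e-6)
})

test_that("initialization and forward passes are reproducible for a fixed seed", {
  m1 <- build_model(tiny_cfg(), seed = 11)
  m2 <- build_model(tiny_cfg(), seed = 11)
  expect_identical(m1$params, m2$params)
  x <- matrix(runif(32 * 32), 32)
  expect_identical(predict(m1, x), predict(m2, x))
  m3 <- build_model(tiny_cfg(), seed = 12)
  expect_false(identical(m1$params, m3$params))
})

test_that("parameter gradients agree with finite differences through the graph", {
  # batch norm excluded: its batch statistics make the loss surface too
  # ill-conditioned for finite differences at this tiny scale
  set.seed(42)
  cfg <- tiny_cfg(bn = FALSE)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  tgt <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  for (builder in list(build_unet_baseline, build_model)) {
    m <- builder(cfg, seed = 3)
    loss_of <- function(mm)
      mean((fdacnn:::nn_forward(mm, x, training = TRUE)$out - tgt)^2)
    f <- fdacnn:::nn_forward(m, x, training = TRUE)
    bk <- fdacnn:::nn_backward(m, f, 2 * (f$out - tgt) / length(f$out))
    eps <- 1e-6
    nms <- names(sort(vapply(bk$grads, function(g) max(abs(g)), 0),
                      decreasing = TRUE))[1:8]
    for (nm in nms) {
      g <- bk$grads[[nm]]
      i <- which.max(abs(g))
      m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- m; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      gn <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
      # tolerance accommodates finite-difference noise at relu/pool kinks
      expect_lt(abs(gn - g[i]) / max(abs(gn), abs(g[i])), 1e-2)
    }
  }
})

test_that("model summary exports the audited totals", {
  m <- build_model(model_config(input_size = 64), seed = NULL)
  path <- tempfile(fileext = ".json")
  s <- model_summary(m, path)
  expect_true(file.exists(path))
  js <- jsonlite::read_json(path)
  expect_equal(js$n_conv_layers, 97)
  expect_equal(js$n_dense_blocks, 9)
  unlink(path)
})
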