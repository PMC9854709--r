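#' Training configuration
#'
#' Optimization hyperparameters for supervised de-aliasing training. The
#' defaults follow the reference protocol: Adam with beta1 = 0.9,
#' beta2 = 0.999, initial learning rate 1e-4 decaying by a factor 0.95 every
#' 20 epochs, batch size 8. The default epoch budget there is 2000; choose a
#' small value for desk-scale runs.
#'
#' @param lr0 initial learning rate.
#' @param decay multiplicative learning-rate decay factor, in (0, 1].
#' @param decay_every epochs between decay steps.
#' @param beta1,beta2 Adam moment coefficients.
#' @param batch_size mini-batch size.
#' @param epochs number of training epochs.
#' @param seed integer seed controlling initialization order and shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, decay = 0.95, decay_every = 20L,
                         beta1 = 0.9, beta2 = 0.999, batch_size = 8L,
                         epochs = 2000L, seed = 1L) {
  if (lr0 <= 0) stop("train_config: lr0 must be > 0")
  if (!(decay > 0 && decay <= 1)) stop("train_config: decay must be in (0, 1]")
  if (batch_size < 1) stop("train_config: batch_size must be >= 1")
  structure(list(lr0 = lr0, decay = decay, decay_every = as.integer(decay_every),
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Mean squared error between two images
#'
#' `(1/N) * sum((T - R)^2)` over all N pixels: the training loss of the
#' de-aliasing network.
#'
#' @param target,recon equal-shaped numeric arrays.
#' @return non-negative scalar; zero iff the images are identical.
#' @export
mse_loss <- function(target, recon) {
  if (!all(dim(as.array(target)) == dim(as.array(recon))))
    stop("mse_loss: shape mismatch")
  mean((target - recon)^2)
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr0 * decay^floor(epoch / decay_every)` with `epoch` counted
#' from 0.
#'
#' @param epoch epoch index (0-based).
#' @param config a [train_config()].
#' @return the learning rate.
#' @examples
#' lr_at(20, train_config()) # 9.5e-5
#' @export
lr_at <- function(epoch, config = train_config()) {
  if (any(epoch < 0)) stop("lr_at: epoch must be >= 0")
  config$lr0 * config$decay^floor(epoch / config$decay_every)
}

# Adam update; st holds first/second moments and the step counter.
adam_step <- function(params, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(st$m[[nm]])) { st$m[[nm]] <- g * 0; st$v[[nm]] <- g * 0 }
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

# Stack a list of matrices into an [H, W, 1, N] batch array.
stack_batch <- function(imgs) {
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), c(h, w, 1L, length(imgs)))
}

# Per-image normalization: scale by the max of the zero-filled input (shared
# with the target so the pair stays on one intensity scale).
norm_const <- function(zf) max(max(abs(zf)), 1e-8)

#' Identity-preserving initialization for the de-aliasing network
#'
#' Starts the fully dense attention network close to the identity map, so
#' that short training runs refine the zero-filled input instead of first
#' having to relearn it. Three structural edits route an affine image of the
#' input through the level-1 skip path -- the stem convolution dedicates a
#' +/- delta-kernel channel pair (whose ReLU halves jointly encode the
#' signed input), the level-1 attention gate logit is held constant and
#' nearly open (zero weights, positive bias), and the level-1 decoder
#' reduction passes the pair -- and the output head is then calibrated by
#' least squares on a small batch so the initial network output reproduces
#' its input. All remaining parameters keep their fan-in-scaled random
#' values, and every edited parameter remains trainable.
#'
#' @param model an initialized FDA-CNN `recon_model`.
#' @param calib array H x W x 1 x N (or list of matrices) of representative
#'   network inputs (zero-filled reconstructions) used for head calibration.
#' @return the model with edited initial parameters.
#' @export
init_identity <- function(model, calib) {
  stopifnot(inherits(model, "recon_model"))
  if (!identical(model$arch, "FDA-CNN"))
    stop("init_identity: identity initialization is defined for FDA-CNN")
  if (is.list(calib)) calib <- stack_batch(calib)
  inv <- model$inventory
  pname_of <- function(w) {
    p <- inv$pname[inv$where == w & inv$type == "conv"]
    if (!length(p)) stop("init_identity: layer not found: ", w)
    p[1]
  }
  # stem: channels 1/2 carry +x and -x (center tap of the 3x3 kernel)
  p <- pname_of("stem")
  W <- model$params[[paste0(p, ".W")]]
  W[, , 1, 1] <- 0; W[2, 2, 1, 1] <- 1
  W[, , 1, 2] <- 0; W[2, 2, 1, 2] <- -1
  model$params[[paste0(p, ".W")]] <- W
  model$params[[paste0(p, ".b")]][1:2] <- 0
  # level-1 gate: constant, nearly open attention (alpha = sigmoid(6))
  p_psi <- pname_of("dec1/gate.psi")
  model$params[[paste0(p_psi, ".W")]][] <- 0
  model$params[[paste0(p_psi, ".b")]][] <- 6
  # level-1 reduction: channels 1/2 reconstruct the signed pair
  p_red <- pname_of("dec1/reduce")
  W <- model$params[[paste0(p_red, ".W")]]
  W[, , , 1] <- 0; W[1, 1, 1, 1] <- 1; W[1, 1, 2, 1] <- -1
  W[, , , 2] <- 0; W[1, 1, 1, 2] <- -1; W[1, 1, 2, 2] <- 1
  model$params[[paste0(p_red, ".W")]] <- W
  model$params[[paste0(p_red, ".b")]][1:2] <- 0
  # head: least-squares fit of the pre-head features to the input itself
  head_node <- length(model$nodes)
  stopifnot(model$nodes[[head_node]]$op == "conv")
  fwd <- nn_forward(model, calib, training = TRUE, update_state = FALSE)
  feats <- fwd$acts[[model$nodes[[head_node]]$inputs[1]]]
  d <- dim(feats)
  X <- matrix(aperm(feats, c(1, 2, 4, 3)), ncol = d[3])
  fit <- stats::lm.fit(cbind(1, X), as.vector(calib))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  p_head <- model$nodes[[head_node]]$p
  model$params[[paste0(p_head, ".b")]][] <- co[1]
  Wh <- model$params[[paste0(p_head, ".W")]]
  Wh[1, 1, , 1] <- co[-1]
  model$params[[paste0(p_head, ".W")]] <- Wh
  model
}

#' Train a de-aliasing network
#'
#' Supervised training on (zero-filled input, ground-truth target) pairs.
#' One mask is generated from `mask_spec` at the start and retrospectively
#' applied to every stored k-space (the reference protocol trains one
#' network per sampling pattern); each zero-filled input is normalized by
#' its own maximum, the target sharing the normalization constant. The mean
#' squared error is minimized with Adam under the step-decay learning-rate
#' schedule of [lr_at()].
#'
#' @param model a `recon_model` (parameters are initialized from
#'   `config$seed` if absent).
#' @param data a `phantom_dataset` with non-empty train and val splits.
#' @param mask_spec a [mask_spec()] matching the image size.
#' @param config a [train_config()].
#' @param per_sample_masks if `TRUE`, draw a fresh random mask per sample per
#'   epoch instead of a single fixed mask (extension; off by default).
#' @param identity_init apply [init_identity()] before optimization
#'   (FDA-CNN only; default `TRUE` for FDA-CNN models), calibrating on the
#'   first training inputs so optimization starts at zero-filled fidelity.
#' @param verbose print per-epoch losses.
#' @return list with `model` (final weights), `best_model` (weights at the
#'   best validation loss), `history` (data frame: epoch, train_loss,
#'   val_loss, lr, seconds) and `mask`.
#' @export
train <- function(model, data, mask_spec, config = train_config(),
                  per_sample_masks = FALSE,
                  identity_init = identical(model$arch, "FDA-CNN"),
                  verbose = FALSE) {
  stopifnot(inherits(model, "recon_model"), inherits(data, "phantom_dataset"),
            inherits(mask_spec, "mask_spec"), inherits(config, "train_config"))
  tr_idx <- which(data$split == "train")
  va_idx <- which(data$split == "val")
  if (!length(tr_idx) || !length(va_idx))
    stop("train: need non-empty train and val splits")
  if (is.null(model$params)) model <- init_params(model, config$seed)
  mask <- make_mask(mask_spec)

  prep <- function(i, msk) {
    zf <- zero_filled_recon(data$kspaces[[i]], msk)
    s <- norm_const(zf)
    list(x = zf / s, y = data$images[[i]] / s)
  }
  tr_pairs <- lapply(tr_idx, prep, msk = mask)
  va_pairs <- lapply(va_idx, prep, msk = mask)
  if (identity_init) {
    calib <- lapply(tr_pairs[seq_len(min(8L, length(tr_pairs)))], `[[`, "x")
    model <- init_identity(model, calib)
  }
  va_x <- stack_batch(lapply(va_pairs, `[[`, "x"))
  va_y <- stack_batch(lapply(va_pairs, `[[`, "y"))

  opt <- list(t = 0L, m = list(), v = list())
  hist <- data.frame()
  best <- list(loss = Inf, params = model$params, bn_state = model$bn_state)
  n_tr <- length(tr_pairs)
  bs <- config$batch_size

  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    lr <- lr_at(epoch - 1L, config)
    ord <- with_seed(sub_seed(config$seed, epoch), sample(n_tr))
    if (per_sample_masks) {
      msk_e <- make_mask(mask_spec_with_seed(mask_spec,
                                             sub_seed(mask_spec$seed, epoch)))
      tr_pairs <- lapply(tr_idx, prep, msk = msk_e)
    }
    batch_losses <- c()
    for (b0 in seq(1L, n_tr, by = bs)) {
      sel <- ord[seq(b0, min(b0 + bs - 1L, n_tr))]
      xb <- stack_batch(lapply(tr_pairs[sel], `[[`, "x"))
      yb <- stack_batch(lapply(tr_pairs[sel], `[[`, "y"))
      fwd <- nn_forward(model, xb, training = TRUE)
      model$bn_state <- fwd$bn_state
      resid <- fwd$out - yb
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop(sprintf("train: non-finite loss at epoch %d (divergence)", epoch))
      batch_losses <- c(batch_losses, loss)
      dout <- 2 * resid / length(resid)
      bwd <- nn_backward(model, fwd, dout)
      upd <- adam_step(model$params, bwd$grads, opt, lr,
                       config$beta1, config$beta2)
      model$params <- upd$params
      opt <- upd$st
      rm(fwd, bwd)
    }
    va_out <- nn_forward(model, va_x, training = FALSE)$out
    val_loss <- mean((va_out - va_y)^2)
    if (!is.finite(val_loss))
      stop(sprintf("train: non-finite validation loss at epoch %d", epoch))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = model$params,
                   bn_state = model$bn_state)
    secs <- proc.time()[["elapsed"]] - t0
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(batch_losses),
                                   val_loss = val_loss, lr = lr,
                                   seconds = secs))
    if (verbose)
      message(sprintf("epoch %3d  train %.3e  val %.3e  lr %.2e  %.1fs",
                      epoch, mean(batch_losses), val_loss, lr, secs))
  }
  best_model <- model
  best_model$params <- best$params
  best_model$bn_state <- best$bn_state
  list(model = model, best_model = best_model, history = hist, mask = mask)
}

# clone of a mask_spec with a different seed (per-sample-mask extension)
mask_spec_with_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed %% 2147483123)
  spec
}

#' Reconstruct an image from under-sampled k-space
#'
#' Zero-filled reconstruction followed by the trained network's forward pass
#' (batch-norm in inference mode), undoing the per-image normalization and
#' clipping to the non-negative range.
#'
#' @param model a trained `recon_model`.
#' @param kspace_under under-sampled complex k-space matrix (H x W), or a
#'   list of them.
#' @param mask the `sampling_mask` that produced it (applied again;
#'   idempotent on already-masked data).
#' @return the reconstructed magnitude image (matrix), or a list of them.
#' @export
reconstruct <- function(model, kspace_under, mask) {
  if (is.list(kspace_under) && !is.matrix(kspace_under))
    return(lapply(kspace_under, reconstruct, model = model, mask = mask))
  if (!all(dim(kspace_under) == c(model$input_size, model$input_size)))
    stop("reconstruct: k-space shape does not match the model input size")
  zf <- zero_filled_recon(kspace_under, mask)
  s <- norm_const(zf)
  out <- predict(model, zf / s)
  pmax(out * s, 0)
}
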