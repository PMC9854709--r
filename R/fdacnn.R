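#' Network configuration
#'
#' Hyperparameters of the fully dense attention network and the Unet
#' baseline. The defaults reproduce the reference architecture: five spatial
#' levels, an initial growth rate of 8, 64 feature maps out of the first
#' dense block, and a 32-channel stem convolution. The channel bookkeeping is
#' tied together by the invariant `f_1 = stem_channels + 4 * k_1` (a dense
#' block concatenates its input with four growth-rate-sized layer outputs).
#'
#' @param depth number of spatial levels (encoder dense blocks).
#' @param k_1 growth rate of the level-1 dense block; doubles per level.
#' @param f_1 output feature maps of the level-1 dense block; doubles per
#'   level.
#' @param stem_channels channels produced by the initial 3x3 convolution.
#' @param input_size input image side length; must be divisible by
#'   `2^(depth - 1)`.
#' @param batch_norm apply batch normalization after the convolutions.
#' @return an object of class `model_config`.
#' @export
model_config <- function(depth = 5L, k_1 = 8L, f_1 = 64L, stem_channels = 32L,
                         input_size = 256L, batch_norm = TRUE) {
  depth <- as.integer(depth); k_1 <- as.integer(k_1); f_1 <- as.integer(f_1)
  stem_channels <- as.integer(stem_channels)
  input_size <- as.integer(input_size)
  if (k_1 < 1 || f_1 < 1 || stem_channels < 1)
    stop("model_config: k_1, f_1 and stem_channels must be positive")
  if (f_1 != stem_channels + 4L * k_1)
    stop("model_config: need f_1 = stem_channels + 4 * k_1 (dense concatenation)")
  if (input_size %% 2L^(depth - 1L) != 0L)
    stop("model_config: input_size must be divisible by 2^(depth - 1)")
  structure(list(depth = depth, k_1 = k_1, f_1 = f_1,
                 stem_channels = stem_channels, input_size = input_size,
                 batch_norm = isTRUE(batch_norm)),
            class = "model_config")
}

#' Plan a dense block for a spatial level
#'
#' Applies the level-doubling rule to the initial hyperparameters: the growth
#' rate at level m is `k_m = 2^(m-1) * k_1` and the block output is
#' `f_m = 2^(m-1) * f_1`. The block input width follows from the dense
#' concatenation: `F_in = f_m - 4 * k_m`.
#'
#' @param m spatial level, `1 <= m <= config$depth`.
#' @param config a [model_config()].
#' @return an object of class `dense_block_spec` with fields `m`, `k_m`,
#'   `f_m`, `L` (always 4) and `F_in`.
#' @examples
#' dense_block_plan(5, model_config()) # k_m = 128 on a 512-channel input
#' @export
dense_block_plan <- function(m, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  m <- as.integer(m)
  if (m < 1L || m > config$depth)
    stop("dense_block_plan: level m out of range")
  k_m <- 2L^(m - 1L) * config$k_1
  f_m <- 2L^(m - 1L) * config$f_1
  F_in <- f_m - 4L * k_m
  if (F_in < 1L || F_in + 4L * k_m != f_m)
    stop("dense_block_plan: invariant f_m = F_in + 4 k_m cannot hold")
  structure(list(m = m, k_m = k_m, f_m = f_m, L = 4L, F_in = F_in),
            class = "dense_block_spec")
}

#' Layer inventory of a single dense block
#'
#' Expands a [dense_block_plan()] into its eight convolutions: each of the
#' four dense layers applies a 1x1 convolution compressing the accumulated
#' concatenation back to `F_in` channels, then a 3x3 convolution (padding 1)
#' emitting `k_m` new feature maps; the block output is the concatenation of
#' the block input with all four layer outputs (`f_m` channels).
#'
#' @param spec a `dense_block_spec`.
#' @return a data frame with one row per convolution (`layer`, `type`,
#'   `kernel`, `in_ch`, `out_ch`).
#' @export
build_dense_block <- function(spec) {
  stopifnot(inherits(spec, "dense_block_spec"))
  rows <- list()
  for (l in seq_len(spec$L)) {
    c_in <- spec$F_in + spec$k_m * (l - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = l, type = "conv", kernel = "1x1", in_ch = c_in,
      out_ch = spec$F_in)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = l, type = "conv", kernel = "3x3", in_ch = spec$F_in,
      out_ch = spec$k_m)
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Graph builder helpers. A builder is an environment accumulating nodes,
# parameter shape specs and a human-readable layer inventory.

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$nodes <- list()
  b$pshapes <- list()
  b$inv <- list()
  b$n_param <- 0L
  b
}

add_node <- function(b, op, inputs = integer(0), p = NULL, ...) {
  inputs <- as.integer(inputs) # force: nested add_node calls allocate ids
  id <- length(b$nodes) + 1L
  b$nodes[[id]] <- c(list(id = id, op = op, inputs = inputs, p = p),
                     list(...))
  id
}

new_pname <- function(b) {
  b$n_param <- b$n_param + 1L
  sprintf("p%03d", b$n_param)
}

add_inventory <- function(b, type, kernel, stride, in_ch, out_ch, where,
                          pname = NA_character_) {
  b$inv[[length(b$inv) + 1L]] <- data.frame(
    type = type, kernel = kernel, stride = stride, in_ch = in_ch,
    out_ch = out_ch, where = where, pname = pname)
}

# conv (+ optional BN) (+ optional ReLU); returns output node id
add_conv <- function(b, x, kh, cin, cout, stride = 1L, pad = 0L, bn = TRUE,
                     act = "relu", where = "") {
  p <- new_pname(b)
  b$pshapes[[paste0(p, ".W")]] <- c(kh, kh, cin, cout)
  b$pshapes[[paste0(p, ".b")]] <- cout
  id <- add_node(b, "conv", x, p = p, stride = stride, pad = pad)
  add_inventory(b, "conv", sprintf("%dx%d", kh, kh), stride, cin, cout, where,
                pname = p)
  if (bn) {
    pb <- new_pname(b)
    b$pshapes[[paste0(pb, ".gamma")]] <- cout
    b$pshapes[[paste0(pb, ".beta")]] <- cout
    id <- add_node(b, "bn", id, p = pb)
    add_inventory(b, "bn", "-", 1L, cout, cout, where)
  }
  if (identical(act, "relu")) {
    id <- add_node(b, "relu", id)
  } else if (identical(act, "sigmoid")) {
    id <- add_node(b, "sigmoid", id)
  }
  id
}

add_tconv <- function(b, x, cin, cout, bn = TRUE, act = "relu", where = "") {
  p <- new_pname(b)
  b$pshapes[[paste0(p, ".W")]] <- c(2L, 2L, cin, cout)
  b$pshapes[[paste0(p, ".b")]] <- cout
  id <- add_node(b, "tconv", x, p = p)
  add_inventory(b, "tconv", "2x2", 2L, cin, cout, where, pname = p)
  if (bn) {
    pb <- new_pname(b)
    b$pshapes[[paste0(pb, ".gamma")]] <- cout
    b$pshapes[[paste0(pb, ".beta")]] <- cout
    id <- add_node(b, "bn", id, p = pb)
    add_inventory(b, "bn", "-", 1L, cout, cout, where)
  }
  if (identical(act, "relu")) id <- add_node(b, "relu", id)
  id
}

# dense block subgraph; returns output node id (f_m channels)
add_dense_block_graph <- function(b, x, spec, bn = TRUE, where = "") {
  cur <- x
  for (l in seq_len(spec$L)) {
    c_in <- spec$F_in + spec$k_m * (l - 1L)
    t1 <- add_conv(b, cur, 1L, c_in, spec$F_in, bn = bn,
                   where = sprintf("%s/dense%d.compress", where, l))
    t2 <- add_conv(b, t1, 3L, spec$F_in, spec$k_m, pad = 1L, bn = bn,
                   where = sprintf("%s/dense%d.grow", where, l))
    cur <- add_node(b, "concat", c(cur, t2))
  }
  cur
}

# attention gate subgraph: x at full resolution (F_x channels), g at half
# resolution (F_g channels); returns the gated skip (same shape as x)
add_attention_gate <- function(b, x, g, F_x, F_g, bn = TRUE, where = "") {
  F_int <- max(1L, F_x %/% 2L)
  xs <- add_conv(b, x, 1L, F_x, F_int, stride = 2L, bn = bn, act = "none",
                 where = paste0(where, "/gate.x"))
  gs <- add_conv(b, g, 1L, F_g, F_int, bn = bn, act = "none",
                 where = paste0(where, "/gate.g"))
  s <- add_node(b, "relu", add_node(b, "add", c(xs, gs)))
  # attention logit: no batch norm, so a saturated bias can hold the gate open
  alpha <- add_conv(b, s, 1L, F_int, 1L, bn = FALSE, act = "sigmoid",
                    where = paste0(where, "/gate.psi"))
  alpha_up <- add_node(b, "upbilin", alpha)
  add_node(b, "gatemul", c(x, alpha_up))
}

finish_model <- function(b, arch, config, head_pname) {
  inv <- do.call(rbind, b$inv)
  structure(list(arch = arch, config = config, nodes = b$nodes,
                 pshapes = b$pshapes, params = NULL, bn_state = list(),
                 inventory = inv, head_pname = head_pname,
                 input_size = config$input_size),
            class = "recon_model")
}

# ---------------------------------------------------------------------------

#' Build the fully dense attention network
#'
#' Assembles the de-aliasing network: a 3x3 stem convolution (1 input channel
#' to `stem_channels`), an encoder of `depth` dense blocks with 2x2
#' max-pooling between levels (a channel-preserving 1x1 transition
#' convolution follows each of the three deepest pools), and a decoder of
#' `depth - 1` levels, each consisting of a 2x2 transposed convolution, an
#' attention gate on the same-level encoder skip (gated by the deeper decoder
#' signal), concatenation, a 1x1 reduction convolution and a dense block. A
#' final 1x1 convolution maps back to one channel. With the default
#' configuration the network contains 9 dense blocks and 97 convolutional
#' plus transposed-convolutional layers.
#'
#' @param config a [model_config()].
#' @param seed integer seed for parameter initialization (fan-in-scaled
#'   Gaussian); `NULL` leaves parameters uninitialized.
#' @return an object of class `recon_model`.
#' @examples
#' m <- build_model(model_config(input_size = 64), seed = 1)
#' count_layers(m) # 97
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  if (config$input_size %% 16L != 0L)
    stop("build_model: input_size must be divisible by 16")
  bn <- config$batch_norm
  b <- new_builder()
  x_in <- add_node(b, "input")
  cur <- add_conv(b, x_in, 3L, 1L, config$stem_channels, pad = 1L, bn = bn,
                  where = "stem")
  plans <- lapply(seq_len(config$depth), dense_block_plan, config = config)
  skips <- integer(config$depth)
  for (m in seq_len(config$depth)) {
    cur <- add_dense_block_graph(b, cur, plans[[m]], bn = bn,
                                 where = sprintf("enc%d", m))
    if (m < config$depth) {
      skips[m] <- cur
      cur <- add_node(b, "maxpool", cur)
      if (m >= 2L) {
        # transition convolution after the deeper encoder pools
        cur <- add_conv(b, cur, 1L, plans[[m]]$f_m, plans[[m]]$f_m, bn = bn,
                        where = sprintf("enc%d/transition", m))
      }
    }
  }
  for (l in rev(seq_len(config$depth - 1L))) {
    f_l <- plans[[l]]$f_m
    f_deep <- plans[[l + 1L]]$f_m
    gated <- add_attention_gate(b, skips[l], cur, f_l, f_deep, bn = bn,
                                where = sprintf("dec%d", l))
    up <- add_tconv(b, cur, f_deep, f_l, bn = bn,
                    where = sprintf("dec%d/up", l))
    cat_id <- add_node(b, "concat", c(gated, up))
    red <- add_conv(b, cat_id, 1L, 2L * f_l, plans[[l]]$F_in, bn = bn,
                    where = sprintf("dec%d/reduce", l))
    cur <- add_dense_block_graph(b, red, plans[[l]], bn = bn,
                                 where = sprintf("dec%d", l))
  }
  head_p <- sprintf("p%03d", b$n_param + 1L)
  add_conv(b, cur, 1L, config$f_1, 1L, bn = FALSE, act = "none",
           where = "head")
  model <- finish_model(b, "FDA-CNN", config, head_p)
  if (!is.null(seed)) model <- init_params(model, seed)
  model
}

#' Build the plain Unet baseline
#'
#' Classical five-level encoder/decoder: two 3x3 convolutions per level,
#' 2x2 max-pooling down, 2x2 transposed-convolution up with skip
#' concatenation, and a 1x1 output head -- 23 convolutional and
#' transposed-convolutional layers in total. Channel widths start at
#' `config$f_1` and double per level.
#'
#' @inheritParams build_model
#' @return an object of class `recon_model`.
#' @export
build_unet_baseline <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  if (config$input_size %% 16L != 0L)
    stop("build_unet_baseline: input_size must be divisible by 16")
  bn <- config$batch_norm
  u <- config$f_1 * 2L^(seq_len(config$depth) - 1L)
  b <- new_builder()
  x_in <- add_node(b, "input")
  cur <- x_in
  cin <- 1L
  skips <- integer(config$depth)
  for (m in seq_len(config$depth)) {
    cur <- add_conv(b, cur, 3L, cin, u[m], pad = 1L, bn = bn,
                    where = sprintf("enc%d/conv1", m))
    cur <- add_conv(b, cur, 3L, u[m], u[m], pad = 1L, bn = bn,
                    where = sprintf("enc%d/conv2", m))
    skips[m] <- cur
    if (m < config$depth) cur <- add_node(b, "maxpool", cur)
    cin <- u[m]
  }
  for (l in rev(seq_len(config$depth - 1L))) {
    up <- add_tconv(b, cur, u[l + 1L], u[l], bn = bn,
                    where = sprintf("dec%d/up", l))
    cat_id <- add_node(b, "concat", c(skips[l], up))
    cur <- add_conv(b, cat_id, 3L, 2L * u[l], u[l], pad = 1L, bn = bn,
                    where = sprintf("dec%d/conv1", l))
    cur <- add_conv(b, cur, 3L, u[l], u[l], pad = 1L, bn = bn,
                    where = sprintf("dec%d/conv2", l))
  }
  add_conv(b, cur, 1L, u[1L], 1L, bn = FALSE, act = "none", where = "head")
  model <- finish_model(b, "Unet", config, NULL)
  if (!is.null(seed)) model <- init_params(model, seed)
  model
}

#' Build a pass-through stub model
#'
#' An identity network (no parameters): its forward pass returns the input
#' unchanged. Useful for wiring checks of the reconstruction pipeline -- with
#' the stub, [reconstruct()] must return exactly the zero-filled input.
#'
#' @param input_size image side length.
#' @return an object of class `recon_model` with architecture tag
#'   `"identity"`.
#' @export
build_identity_model <- function(input_size = 64L) {
  b <- new_builder()
  add_node(b, "input")
  structure(list(arch = "identity",
                 config = list(input_size = as.integer(input_size)),
                 nodes = b$nodes, pshapes = list(), params = list(),
                 bn_state = list(),
                 inventory = data.frame(type = character(0)),
                 input_size = as.integer(input_size)),
            class = "recon_model")
}

#' Run a single attention gate
#'
#' Functional form of the gating unit used at every decoder level: the skip
#' features `x` are compressed by a strided 1x1 convolution, the gating
#' signal `g` (half the spatial size of `x`) by a 1x1 convolution; their sum
#' passes through ReLU, a 1x1 convolution to one channel and a sigmoid,
#' giving attention coefficients in (0, 1) which are bilinearly upsampled and
#' multiplied into `x`.
#'
#' @param x array H x W x F_x x N (or H x W x F_x) of skip features.
#' @param g array H/2 x W/2 x F_g x N of gating features.
#' @param seed seed for the gate's (randomly initialized) parameters.
#' @param saturate_open if `TRUE`, zero the logit weights and use a large
#'   positive logit bias so that every attention coefficient is ~1
#'   (diagnostic: the gate becomes a pass-through).
#' @return list with `gated` (same shape as `x`) and `alpha` (H x W x 1 x N
#'   attention coefficients, all strictly in (0, 1)).
#' @export
attention_gate_forward <- function(x, g, seed = 1L, saturate_open = FALSE) {
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  if (length(dim(g)) == 3L) g <- array(g, c(dim(g), 1L))
  if (!all(dim(g)[1:2] * 2L == dim(x)[1:2]))
    stop("attention_gate_forward: g must have half the spatial size of x")
  if (dim(x)[4] != dim(g)[4])
    stop("attention_gate_forward: batch sizes differ")
  F_x <- dim(x)[3]; F_g <- dim(g)[3]
  b <- new_builder()
  nx <- add_node(b, "input")
  ng <- add_node(b, "input")
  out <- add_attention_gate(b, nx, ng, F_x, F_g, bn = FALSE, where = "gate")
  alpha_id <- b$nodes[[out]]$inputs[2]
  model <- structure(list(arch = "gate", nodes = b$nodes, pshapes = b$pshapes,
                          params = NULL, bn_state = list()),
                     class = "recon_model")
  model <- init_params(model, seed)
  if (saturate_open) {
    psi <- names(model$pshapes)[vapply(names(model$pshapes), function(n)
      length(model$pshapes[[n]]) == 4 && model$pshapes[[n]][4] == 1L, TRUE)]
    wname <- psi[length(psi)]
    model$params[[wname]][] <- 0
    model$params[[sub("\\.W$", ".b", wname)]][] <- 20
  }
  # evaluate the two-input DAG: node 1 <- x, node 2 <- g
  acts <- run_graph_multi(model, list(x, g))
  list(gated = acts$out, alpha = acts$acts[[alpha_id]])
}

# graph evaluation when the first nodes are inputs (standalone gate only)
run_graph_multi <- function(model, inputs) {
  nodes <- model$nodes
  n_in <- length(inputs)
  params <- model$params
  acts <- vector("list", length(nodes))
  for (k in seq_along(nodes)) {
    nd <- nodes[[k]]
    if (nd$op == "input") { acts[[k]] <- inputs[[min(k, n_in)]]; next }
    acts_in <- lapply(nd$inputs, function(i) acts[[i]])
    acts[[k]] <- switch(nd$op,
      conv = cpp_conv_fwd(acts_in[[1]], params[[paste0(nd$p, ".W")]],
                          params[[paste0(nd$p, ".b")]], nd$stride, nd$pad),
      relu = { y <- acts_in[[1]]; y[y < 0] <- 0; y },
      sigmoid = 1 / (1 + exp(-acts_in[[1]])),
      add = acts_in[[1]] + acts_in[[2]],
      upbilin = upsample2_bilinear(acts_in[[1]]),
      gatemul = {
        C <- dim(acts_in[[1]])[3]
        acts_in[[1]] * acts_in[[2]][, , rep(1L, C), , drop = FALSE]
      },
      stop("unsupported op in standalone gate: ", nd$op))
  }
  list(out = acts[[length(nodes)]], acts = acts)
}

#' Initialize model parameters
#'
#' Fan-in-scaled Gaussian (He) initialization for convolution weights, zero
#' biases, unit batch-norm scales. Deterministic for a given seed.
#'
#' @param model a `recon_model`.
#' @param seed integer seed.
#' @return the model with `params` filled in.
#' @export
init_params <- function(model, seed = 1L) {
  params <- with_seed(seed, {
    lapply(model$pshapes, function(shp) {
      if (length(shp) == 4L) {
        fan_in <- prod(shp[1:3])
        array(stats::rnorm(prod(shp), sd = sqrt(2 / fan_in)), dim = shp)
      } else if (length(shp) == 1L) {
        numeric(shp) # filled below for gammas
      } else stop("bad parameter shape")
    })
  })
  for (nm in names(params))
    if (endsWith(nm, ".gamma")) params[[nm]] <- params[[nm]] + 1
  model$params <- params
  model$bn_state <- list()
  model
}

#' Count convolutional and transposed-convolutional layers
#'
#' Counts every convolution and transposed convolution in the model's layer
#' inventory, including the three 1x1 convolutions inside each attention
#' gate. Batch-norm, pooling, activation and resampling layers are not
#' counted.
#'
#' @param model a `recon_model`.
#' @return integer layer count.
#' @examples
#' count_layers(build_unet_baseline(model_config(input_size = 64), seed = NULL)) # 23
#' @export
count_layers <- function(model) {
  stopifnot(inherits(model, "recon_model"))
  sum(model$inventory$type %in% c("conv", "tconv"))
}

#' Forward pass of a reconstruction model
#'
#' @param object a `recon_model` with initialized parameters.
#' @param x input: an H x W matrix or an H x W x 1 x N array.
#' @param training use batch statistics in batch-norm layers (and cache
#'   intermediates); otherwise running statistics are used.
#' @param gates_off force all attention coefficients to 1 (diagnostic).
#' @param ... unused.
#' @return output of the same shape as `x`.
#' @export
predict.recon_model <- function(object, x, training = FALSE,
                                gates_off = FALSE, ...) {
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(nrow(x), ncol(x), 1L, 1L))
  if (object$arch == "identity") {
    out <- x
  } else {
    if (is.null(object$params))
      stop("predict.recon_model: model parameters not initialized")
    out <- nn_forward(object, x, training = training,
                      gates_off = gates_off, update_state = FALSE)$out
  }
  if (was_mat) out <- matrix(out, dim(out)[1], dim(out)[2]) else out
}

#' @export
print.recon_model <- function(x, ...) {
  np <- if (is.null(x$params)) 0 else sum(vapply(x$params, length, 1L))
  cat(sprintf("<recon_model> %s  input %dx%d  %d conv/tconv layers  %d parameters\n",
              x$arch, x$input_size, x$input_size, count_layers(x), np))
  invisible(x)
}

#' Export an architecture summary
#'
#' Writes (or returns) a JSON-able summary: configuration, the full layer
#' inventory with channel counts, the number of dense blocks and the counted
#' conv/tconv total.
#'
#' @param model a `recon_model`.
#' @param path optional path of a JSON file to write.
#' @return the summary list, invisibly if `path` is given.
#' @export
model_summary <- function(model, path = NULL) {
  stopifnot(inherits(model, "recon_model"))
  n_dense <- if (nrow(model$inventory))
    length(unique(sub("/dense[0-9]+\\..*$", "",
                      grep("/dense[0-9]+\\.", model$inventory$where,
                           value = TRUE)))) else 0L
  out <- list(arch = model$arch,
              config = unclass(model$config),
              n_conv_layers = count_layers(model),
              n_dense_blocks = n_dense,
              n_parameters = if (is.null(model$params)) 0L else
                sum(vapply(model$params, length, 1L)),
              inventory = model$inventory)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(out))
  }
  out
}
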