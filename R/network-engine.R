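# Minimal static-graph engine for the reconstruction networks.
#
# A model holds an ordered list of nodes (a DAG in topological order); each
# node names an operation, its input node ids, and optionally a parameter
# prefix. Forward evaluation caches whatever the hand-written backward pass
# of each operation needs. Tensors are R arrays [H, W, C, N].

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# --- bilinear 2x upsampling -------------------------------------------------
# Factor-2, half-pixel-centered (align_corners = FALSE), edge-clamped. The
# operator is linear, so the backward pass is its transpose.
bilinear_up_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    U <- matrix(0, 2 * n, n)
    for (o in seq_len(2 * n)) {
      pos <- (o - 0.5) / 2 + 0.5   # fractional source position, 1-based
      lo <- floor(pos)
      frac <- pos - lo
      lo_c <- min(max(lo, 1), n)
      hi_c <- min(max(lo + 1, 1), n)
      U[o, lo_c] <- U[o, lo_c] + (1 - frac)
      U[o, hi_c] <- U[o, hi_c] + frac
    }
    cache[[key]] <- U
    U
  }
})

upsample2_bilinear <- function(x) {
  d <- dim(x)
  U <- bilinear_up_matrix(d[1])
  V <- bilinear_up_matrix(d[2])
  y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  for (n in seq_len(d[4]))
    for (c in seq_len(d[3]))
      y[, , c, n] <- U %*% x[, , c, n] %*% t(V)
  y
}

upsample2_bilinear_bwd <- function(dy, in_dim) {
  U <- bilinear_up_matrix(in_dim[1])
  V <- bilinear_up_matrix(in_dim[2])
  dx <- array(0, in_dim)
  for (n in seq_len(in_dim[4]))
    for (c in seq_len(in_dim[3]))
      dx[, , c, n] <- t(U) %*% dy[, , c, n] %*% V
  dx
}

# --- forward ----------------------------------------------------------------

#' @keywords internal
nn_forward <- function(model, x, training = FALSE, gates_off = FALSE,
                       update_state = training) {
  nodes <- model$nodes
  params <- model$params
  state <- model$bn_state
  acts <- vector("list", length(nodes))
  ctx <- vector("list", length(nodes))
  for (k in seq_along(nodes)) {
    nd <- nodes[[k]]
    acts_in <- lapply(nd$inputs, function(i) acts[[i]])
    a <- switch(nd$op,
      input = x,
      conv = cpp_conv_fwd(acts_in[[1]], params[[paste0(nd$p, ".W")]],
                          params[[paste0(nd$p, ".b")]],
                          nd$stride, nd$pad),
      tconv = cpp_tconv2_fwd(acts_in[[1]], params[[paste0(nd$p, ".W")]],
                             params[[paste0(nd$p, ".b")]]),
      bn = {
        g <- params[[paste0(nd$p, ".gamma")]]
        b <- params[[paste0(nd$p, ".beta")]]
        if (training) {
          r <- cpp_bn_fwd(acts_in[[1]], g, b, BN_EPS)
          ctx[[k]] <- list(mean = r$mean, invstd = r$invstd)
          if (update_state) {
            st <- state[[nd$p]]
            if (is.null(st)) st <- list(mean = r$mean * 0, var = r$var * 0 + 1)
            state[[nd$p]] <- list(
              mean = BN_MOMENTUM * st$mean + (1 - BN_MOMENTUM) * r$mean,
              var = BN_MOMENTUM * st$var + (1 - BN_MOMENTUM) * r$var)
          }
          r$y
        } else {
          st <- state[[nd$p]]
          if (is.null(st)) {
            dimc <- dim(acts_in[[1]])[3]
            st <- list(mean = numeric(dimc), var = rep(1, dimc))
          }
          cpp_bn_eval(acts_in[[1]], g, b, st$mean, st$var, BN_EPS)
        }
      },
      relu = { y <- acts_in[[1]]; y[y < 0] <- 0; y },
      sigmoid = 1 / (1 + exp(-acts_in[[1]])),
      add = acts_in[[1]] + acts_in[[2]],
      maxpool = {
        r <- cpp_maxpool2_fwd(acts_in[[1]])
        ctx[[k]] <- list(idx = r$idx, in_dim = dim(acts_in[[1]]))
        r$y
      },
      upbilin = upsample2_bilinear(acts_in[[1]]),
      concat = {
        d1 <- dim(acts_in[[1]]); d2 <- dim(acts_in[[2]])
        y <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
        y[, , seq_len(d1[3]), ] <- acts_in[[1]]
        y[, , d1[3] + seq_len(d2[3]), ] <- acts_in[[2]]
        ctx[[k]] <- list(split = d1[3])
        y
      },
      gatemul = {
        a0 <- acts_in[[1]]
        alpha <- acts_in[[2]]
        if (gates_off) alpha <- alpha * 0 + 1
        C <- dim(a0)[3]
        a0 * alpha[, , rep(1L, C), , drop = FALSE]
      },
      stop("unknown op: ", nd$op)
    )
    acts[[k]] <- a
  }
  list(out = acts[[length(nodes)]], acts = acts, ctx = ctx, bn_state = state)
}

# --- backward ---------------------------------------------------------------

#' @keywords internal
nn_backward <- function(model, fwd, dout, gates_off = FALSE) {
  nodes <- model$nodes
  params <- model$params
  acts <- fwd$acts
  ctx <- fwd$ctx
  gacts <- vector("list", length(nodes))
  grads <- list()
  gacts[[length(nodes)]] <- dout
  add_grad <- function(lst, i, g) {
    if (is.null(lst[[i]])) lst[[i]] <- g else lst[[i]] <- lst[[i]] + g
    lst
  }
  for (k in rev(seq_along(nodes))) {
    nd <- nodes[[k]]
    dy <- gacts[[k]]
    if (is.null(dy) || nd$op == "input") next
    ins <- nd$inputs
    switch(nd$op,
      conv = {
        r <- cpp_conv_bwd(acts[[ins[1]]], params[[paste0(nd$p, ".W")]], dy,
                          nd$stride, nd$pad)
        grads[[paste0(nd$p, ".W")]] <- r$dw
        grads[[paste0(nd$p, ".b")]] <- r$db
        gacts <- add_grad(gacts, ins[1], r$dx)
      },
      tconv = {
        r <- cpp_tconv2_bwd(acts[[ins[1]]], params[[paste0(nd$p, ".W")]], dy)
        grads[[paste0(nd$p, ".W")]] <- r$dw
        grads[[paste0(nd$p, ".b")]] <- r$db
        gacts <- add_grad(gacts, ins[1], r$dx)
      },
      bn = {
        r <- cpp_bn_bwd(acts[[ins[1]]], dy, params[[paste0(nd$p, ".gamma")]],
                        ctx[[k]]$mean, ctx[[k]]$invstd)
        grads[[paste0(nd$p, ".gamma")]] <- r$dgamma
        grads[[paste0(nd$p, ".beta")]] <- r$dbeta
        gacts <- add_grad(gacts, ins[1], r$dx)
      },
      relu = {
        m <- acts[[ins[1]]] > 0
        gacts <- add_grad(gacts, ins[1], dy * m)
      },
      sigmoid = {
        y <- acts[[k]]
        gacts <- add_grad(gacts, ins[1], dy * y * (1 - y))
      },
      add = {
        gacts <- add_grad(gacts, ins[1], dy)
        gacts <- add_grad(gacts, ins[2], dy)
      },
      maxpool = {
        d <- ctx[[k]]$in_dim
        gacts <- add_grad(gacts, ins[1], cpp_maxpool2_bwd(ctx[[k]]$idx, dy,
                                                          d[1], d[2]))
      },
      upbilin = {
        gacts <- add_grad(gacts, ins[1],
                          upsample2_bilinear_bwd(dy, dim(acts[[ins[1]]])))
      },
      concat = {
        s <- ctx[[k]]$split
        d <- dim(dy)
        gacts <- add_grad(gacts, ins[1], dy[, , seq_len(s), , drop = FALSE])
        gacts <- add_grad(gacts, ins[2],
                          dy[, , s + seq_len(d[3] - s), , drop = FALSE])
      },
      gatemul = {
        x0 <- acts[[ins[1]]]
        alpha <- acts[[ins[2]]]
        C <- dim(x0)[3]
        if (gates_off) {
          gacts <- add_grad(gacts, ins[1], dy)
        } else {
          arep <- alpha[, , rep(1L, C), , drop = FALSE]
          gacts <- add_grad(gacts, ins[1], dy * arep)
          da <- dy * x0
          da <- array(rowSums(aperm(da, c(1, 2, 4, 3)), dims = 3),
                      c(dim(x0)[1], dim(x0)[2], 1, dim(x0)[4]))
          gacts <- add_grad(gacts, ins[2], da)
        }
      },
      stop("no backward for op: ", nd$op)
    )
    if (k > 1) gacts[k] <- list(NULL) # free memory early
  }
  list(grads = grads, dx = gacts[[1]])
}
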