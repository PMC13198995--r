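# Reverse-mode automatic differentiation over 4-d (H, W, C, N) arrays.
#
# A node is an environment holding the forward value `v`, the accumulated
# cotangent `g`, the list of parent nodes, and a `backward` closure that
# pushes `g` into the parents.  Graphs are built define-by-run; calling
# ag_backward() walks the tape in reverse topological order.  Trainable
# parameters are nodes without parents whose gradients persist until the
# optimiser consumes them.

ag_tensor <- function(v, parents = list(), name = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$parents <- parents
  e$backward <- NULL
  e$name <- name
  e$is_param <- FALSE
  class(e) <- "ag_tensor"
  e
}

ag_param <- function(v, name) {
  e <- ag_tensor(v, name = name)
  e$is_param <- TRUE
  e
}

ag_accum <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

# Reverse topological order by iterative depth-first post-order.
ag_topo <- function(root) {
  order <- vector("list", 64L)
  n_ord <- 0L
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$stage == 1L) {
      if (isTRUE(node$.visited)) next
      node$.visited <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (!isTRUE(p$.visited)) stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  order <- order[seq_len(n_ord)]
  for (nd in order) nd$.visited <- NULL
  rev(order)
}

# Backpropagate `seed` (an array shaped like root$v) through the tape.
# Non-parameter intermediate gradients are released as soon as consumed.
ag_backward <- function(root, seed) {
  root$g <- seed
  for (node in ag_topo(root)) {
    if (!is.null(node$backward) && !is.null(node$g)) node$backward(node$g)
    if (!node$is_param) node$g <- NULL
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- primitive operations -------------------------------------------------

# `cache = TRUE` (training) retains the im2col matrix from the forward pass
# for reuse in the backward pass.  The input gradient is skipped for leaf
# inputs that are not parameters (e.g. the image batch feeding the stem).
ag_conv2d <- function(x, layer, cache = FALSE) {
  use_cache <- cache && layer$groups == 1L
  res <- cpp_conv2d_fwd(x$v, layer$w$v, layer$stride, layer$pad[1], layer$pad[2],
                        layer$pad[3], layer$pad[4], layer$dil, layer$groups,
                        use_cache)
  if (use_cache) {
    y <- res$y
    col_cache <- res$cache
  } else {
    y <- res
    col_cache <- NULL
  }
  if (!is.null(layer$b)) {
    cn <- dim(y)[3]
    y <- cpp_channel_affine(y, rep(1, cn), layer$b$v)
  }
  parents <- if (is.null(layer$b)) list(x, layer$w) else list(x, layer$w, layer$b)
  need_dx <- x$is_param || length(x$parents) > 0L || !is.null(x$backward)
  out <- ag_tensor(y, parents)
  out$backward <- function(dy) {
    bw <- cpp_conv2d_bwd(x$v, layer$w$v, dy, layer$stride, layer$pad[1],
                         layer$pad[2], layer$pad[3], layer$pad[4],
                         layer$dil, layer$groups, col_cache, need_dx)
    if (need_dx || layer$groups != 1L) ag_accum(x, bw$dx)
    ag_accum(layer$w, bw$dw)
    if (!is.null(layer$b)) ag_accum(layer$b, rowSums(cpp_channel_sums(dy)))
  }
  out
}

ag_batchnorm <- function(x, layer, training) {
  d <- dim(x$v)
  C <- d[3]; N <- d[4]
  m <- prod(d[c(1, 2, 4)])
  eps <- layer$eps
  if (training && N >= 1L) {
    red <- cpp_bn_reduce(x$v)
    mu <- red[1, ] / m
    var <- pmax(red[2, ] / m - mu^2, 0)
    layer$rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * mu
    layer$rvar <- (1 - layer$momentum) * layer$rvar + layer$momentum * var
  } else {
    mu <- layer$rmean
    var <- layer$rvar
  }
  invstd <- 1 / sqrt(var + eps)
  scale <- layer$gamma$v * invstd
  y <- cpp_channel_affine(x$v, scale, layer$beta$v - mu * scale)
  out <- ag_tensor(y, list(x, layer$gamma, layer$beta))
  out$backward <- function(dy) {
    xhat <- cpp_channel_affine(x$v, invstd, -mu * invstd)
    red <- cpp_bn_reduce2(dy, xhat)
    dbeta <- red[1, ]
    dgamma <- red[2, ]
    ag_accum(layer$gamma, dgamma)
    ag_accum(layer$beta, dbeta)
    if (training) {
      s1 <- layer$gamma$v * invstd
      dx <- cpp_channel_affine(dy, s1, -s1 * dbeta / m) +
        cpp_channel_affine(xhat, -s1 * dgamma / m, rep(0, C))
    } else {
      dx <- cpp_channel_affine(dy, layer$gamma$v * invstd, rep(0, C))
    }
    ag_accum(x, dx)
  }
  out
}

ag_relu <- function(x) {
  y <- x$v
  y[y < 0] <- 0
  out <- ag_tensor(y, list(x))
  out$backward <- function(dy) ag_accum(x, dy * (x$v > 0))
  out
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$v))
  out <- ag_tensor(y, list(x))
  out$backward <- function(dy) ag_accum(x, dy * y * (1 - y))
  out
}

# swish / SiLU: x * sigmoid(x), the EfficientNet activation
ag_swish <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  out <- ag_tensor(x$v * s, list(x))
  out$backward <- function(dy) ag_accum(x, dy * (s + x$v * s * (1 - s)))
  out
}

ag_add <- function(a, b) {
  out <- ag_tensor(a$v + b$v, list(a, b))
  out$backward <- function(dy) {
    ag_accum(a, dy)
    ag_accum(b, dy)
  }
  out
}

# x scaled per channel per sample by s with dim (1, 1, C, N) (SE / attention
# gating); gradients flow to both factors.
ag_scale_channels <- function(x, s) {
  d <- dim(x$v)
  sc <- as.vector(s$v)
  y <- cpp_channel_affine(x$v, sc, rep(0, length(sc)))
  out <- ag_tensor(y, list(x, s))
  out$backward <- function(dy) {
    ag_accum(x, cpp_channel_affine(dy, sc, rep(0, length(sc))))
    ds <- cpp_channel_sums(dy * x$v)
    dim(ds) <- dim(s$v)
    ag_accum(s, ds)
  }
  out
}

ag_concat <- function(xs) {
  dims <- lapply(xs, function(t) dim(t$v))
  cc <- vapply(dims, `[`, integer(1), 3L)
  d1 <- dims[[1]]
  y <- array(0, c(d1[1], d1[2], sum(cc), d1[4]))
  hi <- cumsum(cc)
  lo <- c(1L, utils::head(hi, -1L) + 1L)
  for (i in seq_along(xs)) y[, , lo[i]:hi[i], ] <- xs[[i]]$v
  out <- ag_tensor(y, xs)
  out$backward <- function(dy) {
    for (i in seq_along(xs)) {
      g <- dy[, , lo[i]:hi[i], , drop = FALSE]
      ag_accum(xs[[i]], g)
    }
  }
  out
}

ag_global_avgpool <- function(x) {
  y <- cpp_adaptive_avgpool_fwd(x$v, 1L, 1L)
  d <- dim(x$v)
  out <- ag_tensor(y, list(x))
  out$backward <- function(dy) ag_accum(x, cpp_adaptive_avgpool_bwd(dy, d[1], d[2]))
  out
}

ag_adaptive_avgpool <- function(x, oh, ow) {
  y <- cpp_adaptive_avgpool_fwd(x$v, as.integer(oh), as.integer(ow))
  d <- dim(x$v)
  out <- ag_tensor(y, list(x))
  out$backward <- function(dy) ag_accum(x, cpp_adaptive_avgpool_bwd(dy, d[1], d[2]))
  out
}

ag_resize_bilinear <- function(x, oh, ow) {
  y <- cpp_resize_bilinear_fwd(x$v, as.integer(oh), as.integer(ow))
  d <- dim(x$v)
  out <- ag_tensor(y, list(x))
  out$backward <- function(dy) ag_accum(x, cpp_resize_bilinear_bwd(dy, d[1], d[2]))
  out
}
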