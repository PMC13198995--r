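# Layer constructors and the network registry.
#
# A network (`net`) is an environment collecting every trainable parameter
# (for the optimiser and checkpointing) and every convolution layer (for
# the analytic FLOPs ledger).  Layer constructors are given the incoming
# spatial size so output shapes are known at build time without a forward
# pass.

new_net <- function() {
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$convs <- list()
  net$bns <- list()
  net
}

net_register_param <- function(net, p) {
  net$params[[length(net$params) + 1L]] <- p
  p
}

# Truncated-normal variance-scaling initialisation (fan-out, scale 2), the
# convention of the EfficientNet reference implementation.
init_conv_weight <- function(kh, kw, cin_g, cout, groups = 1L) {
  fan_out <- if (groups > 1L) kh * kw else kh * kw * cout
  sd <- sqrt(2 / fan_out)
  n <- kh * kw * cin_g * cout
  w <- stats::rnorm(n, sd = sd)
  oob <- abs(w) > 2 * sd
  while (any(oob)) {
    w[oob] <- stats::rnorm(sum(oob), sd = sd)
    oob <- abs(w) > 2 * sd
  }
  array(w, c(kh, kw, cin_g, cout))
}

# Padding for "same"-style convolutions.  Stride 1 pads symmetrically;
# stride 2 over even inputs pads asymmetrically (k%/%2 - 1 before, k%/%2
# after), reproducing the zero-padding the EfficientNet graph applies ahead
# of its downsampling convolutions.
same_pad <- function(k, stride, dil = 1L, in_size = NULL) {
  eff <- (k - 1L) * dil + 1L
  if (stride == 1L) {
    p <- (eff - 1L) %/% 2L
    c(p, p, p, p)
  } else {
    stopifnot(stride == 2L)
    odd <- !is.null(in_size) && (in_size %% 2L == 1L)
    p0 <- eff %/% 2L - if (odd) 0L else 1L
    p1 <- eff %/% 2L
    c(p0, p1, p0, p1)
  }
}

new_conv <- function(net, name, kh, kw, cin, cout, in_hw,
                     stride = 1L, dil = 1L, groups = 1L, bias = FALSE,
                     pad = NULL) {
  cin_g <- cin %/% groups
  if (is.null(pad)) pad <- same_pad(kh, stride, dil, in_hw[1])
  layer <- new.env(parent = emptyenv())
  layer$name <- name
  layer$kh <- kh; layer$kw <- kw
  layer$cin <- cin; layer$cout <- cout
  layer$stride <- stride; layer$dil <- dil; layer$groups <- groups
  layer$pad <- as.integer(pad)
  layer$w <- net_register_param(net, ag_param(init_conv_weight(kh, kw, cin_g, cout, groups),
                                             paste0(name, ".w")))
  layer$b <- NULL
  if (bias) layer$b <- net_register_param(net, ag_param(rep(0, cout), paste0(name, ".b")))
  eff_h <- (kh - 1L) * dil + 1L
  eff_w <- (kw - 1L) * dil + 1L
  layer$out_hw <- c((in_hw[1] + pad[1] + pad[2] - eff_h) %/% stride + 1L,
                    (in_hw[2] + pad[3] + pad[4] - eff_w) %/% stride + 1L)
  net$convs[[length(net$convs) + 1L]] <- layer
  layer
}

new_batchnorm <- function(net, name, C, momentum = 0.1, eps = 1e-3) {
  layer <- new.env(parent = emptyenv())
  layer$name <- name
  layer$momentum <- momentum
  layer$eps <- eps
  layer$gamma <- net_register_param(net, ag_param(rep(1, C), paste0(name, ".gamma")))
  layer$beta <- net_register_param(net, ag_param(rep(0, C), paste0(name, ".beta")))
  layer$rmean <- rep(0, C)
  layer$rvar <- rep(1, C)
  net$bns[[length(net$bns) + 1L]] <- layer
  layer
}

# conv -> BN -> activation, the workhorse composite
new_conv_bn <- function(net, name, k, cin, cout, in_hw, stride = 1L, dil = 1L,
                        groups = 1L, act = "swish") {
  list(conv = new_conv(net, name, k, k, cin, cout, in_hw,
                       stride = stride, dil = dil, groups = groups),
       bn = new_batchnorm(net, paste0(name, ".bn"), cout),
       act = act)
}

fwd_conv_bn <- function(m, x, training) {
  h <- ag_batchnorm(ag_conv2d(x, m$conv, cache = training), m$bn, training)
  switch(m$act,
         swish = ag_swish(h),
         relu = ag_relu(h),
         linear = h,
         stop("unknown activation: ", m$act))
}

# Deep-copied parameter values / restore, for best-weight checkpointing and
# on-disk serialisation.
net_get_weights <- function(net) {
  w <- lapply(net$params, function(p) p$v + 0)  # force a copy: the
  # optimiser updates parameter buffers in place
  names(w) <- vapply(net$params, function(p) p$name, character(1))
  w
}

net_set_weights <- function(net, weights) {
  nm <- vapply(net$params, function(p) p$name, character(1))
  if (!setequal(nm, names(weights)))
    stop("weight list does not match the model's parameter set")
  for (p in net$params) {
    wv <- weights[[p$name]]
    if (length(wv) != length(p$v)) stop("weight shape mismatch for ", p$name)
    wv <- wv + 0  # detach from the caller's list before in-place updates
    if (!is.null(dim(p$v))) dim(wv) <- dim(p$v)
    p$v <- wv
  }
  invisible(net)
}

# BN running statistics travel with checkpoints as well.
net_collect_bn <- function(bns) {
  s <- lapply(bns, function(b) list(rmean = b$rmean, rvar = b$rvar))
  names(s) <- vapply(bns, function(b) b$name, character(1))
  s
}

net_restore_bn <- function(bns, state) {
  for (b in bns) {
    st <- state[[b$name]]
    if (!is.null(st)) {
      b$rmean <- st$rmean
      b$rvar <- st$rvar
    }
  }
  invisible(NULL)
}
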