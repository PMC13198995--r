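# Multi-Scale Feature Fusion (MSFF) skip refinement.
#
# Each skip feature map passes through three parallel branches -- a 1x1
# convolution (channel mixing), a 3x3 convolution (local spatial context)
# and a 3x3 dilated convolution with rate 2 (enlarged receptive field at
# unchanged cost) -- each to C channels with BN + ReLU.  The branch outputs
# are concatenated to 3C channels and gated by a squeeze-and-excitation
# style channel attention (global average pooling, a 3C -> 3C/r -> 3C
# bottleneck with ReLU inside and a sigmoid outside).  The gated map is
# reduced back to C channels by a 1x1 convolution + BN and added to a 1x1
# convolution + BN projection of the block input (the residual path), so
# the block preserves both the spatial size and the channel count of its
# input.  An alternative "wide residual" wiring, in which the residual
# projection goes up to 3C and no reduction is applied, is available behind
# a flag for experimentation; the default wiring is the one consistent
# with the decoder's channel schedule.

new_msff <- function(net, name, C, hw, dilation = 2L, attention_reduction = 8L,
                     wide_residual = FALSE) {
  C <- as.integer(C)
  c3 <- 3L * C
  att_ch <- max(1L, c3 %/% as.integer(attention_reduction))
  m <- list(name = name, C = C, cat_channels = c3, wide = wide_residual)
  m$b1 <- new_conv_bn(net, paste0(name, "_b1"), 1L, C, C, hw, act = "relu")
  m$b2 <- new_conv_bn(net, paste0(name, "_b2"), 3L, C, C, hw, act = "relu")
  m$b3 <- new_conv_bn(net, paste0(name, "_b3"), 3L, C, C, hw,
                      dil = as.integer(dilation), act = "relu")
  m$att_fc1 <- new_conv(net, paste0(name, "_att_fc1"), 1L, 1L, c3, att_ch,
                        c(1L, 1L), bias = TRUE)
  m$att_fc2 <- new_conv(net, paste0(name, "_att_fc2"), 1L, 1L, att_ch, c3,
                        c(1L, 1L), bias = TRUE)
  if (wide_residual) {
    m$res <- list(conv = new_conv(net, paste0(name, "_res"), 1L, 1L, C, c3, hw),
                  bn = new_batchnorm(net, paste0(name, "_res.bn"), c3),
                  act = "linear")
  } else {
    m$reduce <- list(conv = new_conv(net, paste0(name, "_reduce"), 1L, 1L, c3, C, hw),
                     bn = new_batchnorm(net, paste0(name, "_reduce.bn"), C),
                     act = "linear")
    m$res <- list(conv = new_conv(net, paste0(name, "_res"), 1L, 1L, C, C, hw),
                  bn = new_batchnorm(net, paste0(name, "_res.bn"), C),
                  act = "linear")
  }
  m
}

fwd_msff <- function(m, x, training, internals = FALSE) {
  f1 <- fwd_conv_bn(m$b1, x, training)
  f2 <- fwd_conv_bn(m$b2, x, training)
  f3 <- fwd_conv_bn(m$b3, x, training)
  fcat <- ag_concat(list(f1, f2, f3))
  s <- ag_global_avgpool(fcat)
  s <- ag_relu(ag_conv2d(s, m$att_fc1))
  s <- ag_sigmoid(ag_conv2d(s, m$att_fc2))
  gated <- ag_scale_channels(fcat, s)
  res <- fwd_conv_bn(m$res, x, training)
  out <- if (m$wide) {
    ag_add(res, gated)
  } else {
    ag_add(res, fwd_conv_bn(m$reduce, gated, training))
  }
  if (internals) list(out = out, f_cat = fcat, attention = s) else out
}

#' Apply a multi-scale feature fusion block to a feature map
#'
#' Builds a standalone, randomly initialised MSFF block for the input's
#' channel count and runs it in inference mode.  With
#' `return_internals = TRUE` the concatenated three-branch map and the
#' attention gate are returned alongside the output, which is how the
#' block's channel arithmetic (3C concatenation, C output) can be
#' inspected directly.
#'
#' @param x `(H, W, C)` array or `(H, W, C, N)` batch.
#' @param dilation Dilation rate of the third branch (default 2).
#' @param attention_reduction Bottleneck ratio `r` of the channel
#'   attention, giving `3C/r` hidden units (default 8).
#' @param wide_residual Use the 3C-channel residual wiring instead of the
#'   default C-channel output (experimental).
#' @param seed Seed for the block's random initialisation.
#' @param return_internals Also return `f_cat` and `attention`.
#' @return The refined map, or a list `(out, f_cat, attention)`.
#' @export
msff_forward <- function(x, dilation = 2L, attention_reduction = 8L,
                         wide_residual = FALSE, seed = 42L,
                         return_internals = FALSE) {
  if (!all(is.finite(x))) stop("MSFF input contains non-finite values")
  d <- dim(x)
  squeeze <- length(d) == 3L
  if (squeeze) dim(x) <- c(d, 1L)
  d <- dim(x)
  net <- new_net()
  withr_seed(seed, {
    m <- new_msff(net, "msff", d[3], d[1:2], dilation, attention_reduction,
                  wide_residual)
  })
  res <- fwd_msff(m, ag_tensor(x), training = FALSE, internals = TRUE)
  drop1 <- function(a) { if (squeeze) dim(a) <- dim(a)[1:3]; a }
  if (return_internals) {
    list(out = drop1(res$out$v), f_cat = drop1(res$f_cat$v),
         attention = as.vector(res$attention$v))
  } else {
    drop1(res$out$v)
  }
}
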