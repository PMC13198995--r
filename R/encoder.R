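# EfficientNetB0 encoder with four skip taps and the bottleneck map.
#
# The backbone follows the published EfficientNetB0 layout: a stride-2 stem,
# seven MBConv stages (mobile inverted bottlenecks with squeeze-and-
# excitation), and a 1x1 head convolution to 1280 channels.  Skip features
# are tapped at the expansion activations of blocks 2a, 3a, 4a and 6a --
# the tensors immediately before each stride-2 depthwise convolution --
# giving, for a 256x256 input, maps of 128^2x96, 64^2x144, 32^2x240 and
# 16^2x672, with the 8^2x1280 head output as the bottleneck.

effb0_blocks <- function() {
  list(
    list(e = 1L, k = 3L, s = 1L, cin = 32L, cout = 16L, rep = 1L, id = "1"),
    list(e = 6L, k = 3L, s = 2L, cin = 16L, cout = 24L, rep = 2L, id = "2"),
    list(e = 6L, k = 5L, s = 2L, cin = 24L, cout = 40L, rep = 2L, id = "3"),
    list(e = 6L, k = 3L, s = 2L, cin = 40L, cout = 80L, rep = 3L, id = "4"),
    list(e = 6L, k = 5L, s = 1L, cin = 80L, cout = 112L, rep = 3L, id = "5"),
    list(e = 6L, k = 5L, s = 2L, cin = 112L, cout = 192L, rep = 4L, id = "6"),
    list(e = 6L, k = 3L, s = 1L, cin = 192L, cout = 320L, rep = 1L, id = "7")
  )
}

# One MBConv repeat.  `tap` marks repeats whose expansion activation feeds a
# skip connection.
new_mbconv <- function(net, name, cin, cout, k, stride, expand, hw, tap = FALSE) {
  b <- list(name = name, cin = cin, cout = cout, stride = stride,
            expand_ratio = expand, tap = tap)
  cexp <- cin * expand
  if (expand != 1L)
    b$expand <- new_conv_bn(net, paste0(name, "_expand"), 1L, cin, cexp, hw)
  b$dw <- list(conv = new_conv(net, paste0(name, "_dwconv"), k, k, cexp, cexp, hw,
                               stride = stride, groups = cexp),
               bn = new_batchnorm(net, paste0(name, "_dwconv.bn"), cexp),
               act = "swish")
  hw_out <- b$dw$conv$out_hw
  se_ch <- max(1L, cin %/% 4L)
  b$se_reduce <- new_conv(net, paste0(name, "_se_reduce"), 1L, 1L, cexp, se_ch,
                          c(1L, 1L), bias = TRUE)
  b$se_expand <- new_conv(net, paste0(name, "_se_expand"), 1L, 1L, se_ch, cexp,
                          c(1L, 1L), bias = TRUE)
  b$project <- new_conv_bn(net, paste0(name, "_project"), 1L, cexp, cout, hw_out,
                           act = "linear")
  b$residual <- (stride == 1L && cin == cout)
  b$out_hw <- hw_out
  b
}

fwd_mbconv <- function(b, x, training) {
  h <- x
  expand_act <- NULL
  if (!is.null(b[["expand"]])) {
    h <- fwd_conv_bn(b[["expand"]], h, training)
    if (b$tap) expand_act <- h
  } else if (b$tap) {
    expand_act <- h
  }
  h <- fwd_conv_bn(b$dw, h, training)
  # squeeze-and-excitation on the expanded representation
  s <- ag_global_avgpool(h)
  s <- ag_swish(ag_conv2d(s, b$se_reduce))
  s <- ag_sigmoid(ag_conv2d(s, b$se_expand))
  h <- ag_scale_channels(h, s)
  h <- fwd_conv_bn(b$project, h, training)
  if (b$residual) h <- ag_add(h, x)
  list(out = h, expand_act = expand_act)
}

enc_build <- function(net, input_size) {
  hw <- c(input_size, input_size)
  enc <- list(input_size = input_size)
  enc$stem <- new_conv_bn(net, "stem_conv", 3L, 3L, 32L, hw, stride = 2L)
  hw <- enc$stem$conv$out_hw
  taps <- c("block2a", "block3a", "block4a", "block6a")
  blocks <- list()
  for (spec in effb0_blocks()) {
    cin <- spec$cin
    for (r in seq_len(spec$rep)) {
      nm <- paste0("block", spec$id, letters[r])
      stride <- if (r == 1L) spec$s else 1L
      blk <- new_mbconv(net, nm, cin, spec$cout, spec$k, stride, spec$e, hw,
                        tap = nm %in% taps)
      blocks[[nm]] <- blk
      hw <- blk$out_hw
      cin <- spec$cout
    }
  }
  enc$blocks <- blocks
  enc$top <- new_conv_bn(net, "top_conv", 1L, 320L, 1280L, hw)
  enc$out_hw <- hw
  enc
}

enc_forward <- function(enc, x, training) {
  h <- fwd_conv_bn(enc$stem, x, training)
  skips <- list()
  for (blk in enc$blocks) {
    res <- fwd_mbconv(blk, h, training)
    h <- res$out
    if (!is.null(res$expand_act)) skips[[length(skips) + 1L]] <- res$expand_act
  }
  list(skips = skips, bottleneck = fwd_conv_bn(enc$top, h, training))
}

#' Build an EfficientNetB0 encoder
#'
#' Constructs the feature-extraction backbone on its own, outside a full
#' segmentation model, exposing the four skip taps and the bottleneck map.
#' All parameters are trainable.  Pretrained ImageNet weights are not
#' bundled; requesting them falls back to the package's variance-scaling
#' random initialisation with a warning.
#'
#' @param pretrained Logical; request pretrained weights.  When unavailable
#'   (always, in an offline install) a warning is emitted and random
#'   initialisation is used.  Shape and FLOPs behaviour is
#'   weight-independent.
#' @param input_size Side length of the square input; must be divisible by
#'   32 so that the five stride-2 stages land on integer sizes.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `psp_encoder`.
#' @examples
#' enc <- build_encoder(input_size = 64)
#' fp <- encode(enc, array(0, c(64, 64, 3)))
#' vapply(fp$skips, function(s) dim(s)[3], numeric(1))  # 96 144 240 672
#' @export
build_encoder <- function(pretrained = FALSE, input_size = 256L, seed = 42L) {
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32, got ", input_size)
  if (isTRUE(pretrained))
    warning("pretrained ImageNet weights are not available; ",
            "falling back to random initialisation")
  net <- new_net()
  withr_seed(seed, {
    enc <- enc_build(net, input_size)
  })
  obj <- list(net = net, enc = enc, input_size = input_size)
  class(obj) <- "psp_encoder"
  obj
}

#' Run the encoder on an image
#'
#' @param encoder A `psp_encoder` from [build_encoder()].
#' @param image A `(H, W, 3)` array or a `(H, W, 3, N)` batch matching the
#'   encoder's configured input size.
#' @return A feature pyramid: `list(skips = list(S1, S2, S3, S4),
#'   bottleneck = <array>)` with resolutions halving from `input_size/2`
#'   down to `input_size/32` and channel counts 96, 144, 240, 672 and 1280.
#' @export
encode <- function(encoder, image) {
  stopifnot(inherits(encoder, "psp_encoder"))
  x <- as_batch(image, encoder$input_size)
  out <- enc_forward(encoder$enc, ag_tensor(x), training = FALSE)
  list(skips = lapply(out$skips, function(t) t$v),
       bottleneck = out$bottleneck$v)
}

# Coerce an (H,W,3) image or (H,W,3,N) batch to a batch array, validating
# the spatial size against the model configuration.
as_batch <- function(image, input_size) {
  d <- dim(image)
  if (length(d) == 3L) dim(image) <- c(d, 1L)
  d <- dim(image)
  if (length(d) != 4L || d[3] != 3L)
    stop("expected an (H, W, 3) image or (H, W, 3, N) batch")
  if (d[1] != input_size || d[2] != input_size)
    stop("input is ", d[1], "x", d[2], " but the model was built for ",
         input_size, "x", input_size)
  image
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
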