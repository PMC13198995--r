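# Pyramid Pooling Module (PPM) at the bottleneck.
#
# Each branch adaptively average-pools the bottleneck map to a bin grid
# (defaults 1, 2, 3, 6), applies a 1x1 convolution to 128 channels with
# batch normalisation and ReLU, and bilinearly upsamples back to the
# bottleneck resolution.  The input and all branch outputs are concatenated
# (1280 + 4*128 = 1792 channels for the default configuration) and reduced
# to 512 channels by a 1x1 convolution + BN + ReLU.

#' PPM configuration
#'
#' @param bin_sizes Ascending pooling grid sizes; each must not exceed the
#'   spatial size of the map the module is applied to.
#' @param branch_channels Channels of each pooled branch after its 1x1
#'   convolution.
#' @param out_channels Channels after the final reduction convolution.
#' @return A list of class `ppm_config`.
#' @export
ppm_config <- function(bin_sizes = c(1L, 2L, 3L, 6L), branch_channels = 128L,
                       out_channels = 512L) {
  bin_sizes <- as.integer(bin_sizes)
  if (is.unsorted(bin_sizes, strictly = TRUE))
    stop("bin_sizes must be strictly ascending")
  structure(list(bin_sizes = bin_sizes,
                 branch_channels = as.integer(branch_channels),
                 out_channels = as.integer(out_channels)),
            class = "ppm_config")
}

new_ppm <- function(net, cin, hw, config = ppm_config()) {
  if (max(config$bin_sizes) > min(hw))
    stop("PPM bin size ", max(config$bin_sizes), " exceeds the ", hw[1], "x",
         hw[2], " spatial size of the bottleneck map")
  branches <- lapply(seq_along(config$bin_sizes), function(i) {
    b <- config$bin_sizes[i]
    list(bin = b,
         cb = new_conv_bn(net, sprintf("ppm_branch%d", b), 1L, cin,
                          config$branch_channels, c(b, b), act = "relu"))
  })
  ccat <- cin + length(branches) * config$branch_channels
  list(cin = cin, hw = hw, config = config, branches = branches,
       cat_channels = ccat,
       reduce = new_conv_bn(net, "ppm_reduce", 1L, ccat, config$out_channels,
                            hw, act = "relu"))
}

fwd_ppm <- function(ppm, x, training) {
  parts <- list(x)
  for (br in ppm$branches) {
    h <- ag_adaptive_avgpool(x, br$bin, br$bin)
    h <- fwd_conv_bn(br$cb, h, training)
    parts[[length(parts) + 1L]] <- ag_resize_bilinear(h, ppm$hw[1], ppm$hw[2])
  }
  fwd_conv_bn(ppm$reduce, ag_concat(parts), training)
}

#' Apply a pyramid pooling module to a bottleneck map
#'
#' Builds a standalone, randomly initialised PPM block matching the input's
#' channel count and runs it in inference mode.  Intended for inspecting
#' the block in isolation; inside a segmentation model the block is built
#' once and trained end to end.
#'
#' @param bottleneck `(H, W, C)` array or `(H, W, C, N)` batch.
#' @param config A [ppm_config()].
#' @param seed Seed for the block's random initialisation.
#' @return Array with the same spatial size and `config$out_channels`
#'   channels (batch dimension preserved if supplied).
#' @export
ppm_forward <- function(bottleneck, config = ppm_config(), seed = 42L) {
  d <- dim(bottleneck)
  squeeze <- length(d) == 3L
  if (squeeze) dim(bottleneck) <- c(d, 1L)
  d <- dim(bottleneck)
  net <- new_net()
  withr_seed(seed, {
    ppm <- new_ppm(net, d[3], d[1:2], config)
  })
  out <- fwd_ppm(ppm, ag_tensor(bottleneck), training = FALSE)$v
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}
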