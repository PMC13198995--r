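# Whole-model assembly: encoder -> PPM -> five-stage decoder, with the
# three ablation variants, plus the analytic FLOPs ledger.

#' Model configuration
#'
#' @param variant `"full_msff"` (MSFF-refined skips), `"skip_only"` (raw
#'   skip concatenation) or `"no_skip"` (decoder without skip inputs).
#' @param input_size Square input side; divisible by 32.  Bottleneck maps
#'   are `input_size/32` on a side; default pyramid bins larger than the
#'   bottleneck are dropped (with a warning) when building reduced-size
#'   models for desk-scale training.
#' @param decoder_channels Strictly decreasing channel schedule of the five
#'   decoder stages.
#' @param pretrained Request pretrained encoder weights (falls back to
#'   random initialisation with a warning when unavailable).
#' @param attention_reduction MSFF channel-attention bottleneck ratio.
#' @param ppm_bins Pyramid pooling grid sizes.
#' @param msff_wide_residual Experimental 3C-output MSFF wiring.
#' @param seed Integer seed for weight initialisation.
#' @return A list of class `model_config`.
#' @export
model_config <- function(variant = c("full_msff", "skip_only", "no_skip"),
                         input_size = 256L,
                         decoder_channels = c(512L, 256L, 128L, 64L, 32L),
                         pretrained = FALSE,
                         attention_reduction = 8L,
                         ppm_bins = c(1L, 2L, 3L, 6L),
                         msff_wide_residual = FALSE,
                         seed = 42L) {
  variant <- match.arg(variant)
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32, got ", input_size)
  decoder_channels <- as.integer(decoder_channels)
  if (length(decoder_channels) != 5L || any(diff(decoder_channels) >= 0L))
    stop("decoder_channels must be 5 strictly decreasing values")
  if (isTRUE(msff_wide_residual) && variant == "full_msff")
    stop("the wide-residual MSFF wiring changes skip channel counts and is ",
         "not compatible with the decoder schedule; use msff_forward() to ",
         "experiment with it")
  structure(list(variant = variant, input_size = input_size,
                 decoder_channels = decoder_channels,
                 pretrained = isTRUE(pretrained),
                 attention_reduction = as.integer(attention_reduction),
                 ppm_bins = as.integer(ppm_bins),
                 msff_wide_residual = isTRUE(msff_wide_residual),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build a PSP-EffB0-MSFF segmentation model
#'
#' Assembles the EfficientNetB0 encoder, the pyramid pooling bottleneck and
#' the five-stage decoder according to the configured variant.  Decoder
#' stage `i` (for `i` in 1..4) bilinearly doubles the previous map,
#' concatenates the matching skip feature (MSFF-refined, raw, or omitted)
#' and refines with a single 3x3 convolution + BN + ReLU to the stage's
#' channel count; stage 5 upsamples and refines without a skip.  A 1x1
#' convolution + sigmoid head yields the per-pixel liver probability.
#'
#' @param config A [model_config()].
#' @return An object of class `psp_model`.
#' @examples
#' m <- build_model(model_config(input_size = 64, ppm_bins = c(1, 2)))
#' p <- predict(m, array(0, c(64, 64, 3)))
#' dim(p)  # 64 64 1 1
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  if (config$pretrained)
    warning("pretrained ImageNet weights are not available; ",
            "falling back to random initialisation")
  net <- new_net()
  model <- new.env(parent = emptyenv())
  model$net <- net
  model$config <- config
  s <- config$input_size
  withr_seed(config$seed, {
    model$enc <- enc_build(net, s)
    bhw <- model$enc$out_hw
    bins <- config$ppm_bins[config$ppm_bins <= min(bhw)]
    if (length(bins) < length(config$ppm_bins))
      warning("dropping pyramid bins larger than the ", bhw[1], "x", bhw[2],
              " bottleneck: ",
              paste(setdiff(config$ppm_bins, bins), collapse = ", "))
    if (length(bins) == 0L) stop("no usable pyramid bins for this input size")
    model$ppm <- new_ppm(net, 1280L, bhw, ppm_config(bin_sizes = bins))

    skip_ch <- c(96L, 144L, 240L, 672L)
    skip_hw <- lapply(1:4, function(i) c(s, s) %/% (2L^i))
    if (config$variant == "full_msff") {
      model$msff <- lapply(1:4, function(i)
        new_msff(net, sprintf("msff_skip%d", i), skip_ch[i], skip_hw[[i]],
                 dilation = 2L,
                 attention_reduction = config$attention_reduction))
    }
    # decoder: stage i consumes skip (5 - i); stage 5 has no skip
    dch <- config$decoder_channels
    prev_ch <- model$ppm$config$out_channels
    hw <- bhw
    model$stages <- vector("list", 5L)
    for (i in 1:5) {
      hw <- hw * 2L
      skip_i <- if (i <= 4L && config$variant != "no_skip") skip_ch[5L - i] else 0L
      model$stages[[i]] <- list(
        skip_index = if (i <= 4L) 5L - i else NA_integer_,
        refine = new_conv_bn(net, sprintf("dec_stage%d", i), 3L,
                             prev_ch + skip_i, dch[i], hw, act = "relu"))
      prev_ch <- dch[i]
    }
    model$head <- new_conv(net, "head", 1L, 1L, dch[5], 1L, c(s, s), bias = TRUE)
  })
  class(model) <- "psp_model"
  model
}

model_forward_t <- function(model, x, training) {
  enc_out <- enc_forward(model$enc, x, training)
  h <- fwd_ppm(model$ppm, enc_out$bottleneck, training)
  variant <- model$config$variant
  for (i in 1:5) {
    st <- model$stages[[i]]
    d <- dim(h$v)
    h <- ag_resize_bilinear(h, 2L * d[1], 2L * d[2])
    if (!is.na(st$skip_index) && variant != "no_skip") {
      skip <- enc_out$skips[[st$skip_index]]
      if (variant == "full_msff")
        skip <- fwd_msff(model$msff[[st$skip_index]], skip, training)
      h <- ag_concat(list(h, skip))
    }
    h <- fwd_conv_bn(st$refine, h, training)
  }
  ag_sigmoid(ag_conv2d(h, model$head, cache = training))
}

#' Forward pass: per-pixel liver probabilities
#'
#' @param object A `psp_model`.
#' @param image `(H, W, 3)` array or `(H, W, 3, N)` batch at the model's
#'   input size, intensities in `[-1, 1]` (see [preprocess_image()]).
#' @param ... Unused.
#' @return Probability array `(H, W, 1, N)`, all values strictly in (0, 1).
#' @export
predict.psp_model <- function(object, image, ...) {
  x <- as_batch(image, object$config$input_size)
  model_forward_t(object, ag_tensor(x), training = FALSE)$v
}

#' @export
print.psp_model <- function(x, ...) {
  fl <- count_flops(x)
  cat(sprintf("<psp_model> variant=%s input=%dx%d params=%s convs=%d GFLOPs=%.2f\n",
              x$config$variant, x$config$input_size, x$config$input_size,
              format(sum(vapply(x$net$params, function(p) length(p$v), numeric(1))),
                     big.mark = ","),
              length(x$net$convs), fl$gflops))
  invisible(x)
}

#' Analytic FLOPs ledger
#'
#' Counts `2 * Cin/groups * Kh * Kw * Cout * Hout * Wout` floating point
#' operations for every convolution and dense layer in the model
#' (multiply-accumulate counted as two operations; dense layers enter as
#' 1x1 convolutions; depthwise convolutions contribute one input channel
#' per group; biases, normalisation, activation and pooling are excluded).
#'
#' @param model A `psp_model` or `psp_encoder`.
#' @return A list of class `flops_ledger`: `total` (FLOPs), `gflops`, and
#'   `ledger`, a data frame with one row per layer.
#' @export
count_flops <- function(model) {
  if (!inherits(model, c("psp_model", "psp_encoder")))
    stop("count_flops expects a built psp_model or psp_encoder")
  convs <- model$net$convs
  ledger <- do.call(rbind, lapply(convs, function(l) {
    data.frame(layer = l$name,
               type = if (l$groups > 1L) "depthwise_conv"
                      else if (l$kh == 1L && l$kw == 1L) "conv1x1" else "conv",
               c_in = l$cin, c_out = l$cout, k_h = l$kh, k_w = l$kw,
               h_out = l$out_hw[1], w_out = l$out_hw[2], groups = l$groups,
               flops = 2 * (l$cin / l$groups) * l$kh * l$kw * l$cout *
                 l$out_hw[1] * l$out_hw[2],
               stringsAsFactors = FALSE)
  }))
  structure(list(total = sum(ledger$flops), gflops = sum(ledger$flops) / 1e9,
                 ledger = ledger),
            class = "flops_ledger")
}

#' @export
print.flops_ledger <- function(x, ...) {
  cat(sprintf("FLOPs ledger: %d layers, total %.0f FLOPs (%.2f GFLOPs)\n",
              nrow(x$ledger), x$total, x$gflops))
  invisible(x)
}

#' Write the FLOPs ledger to CSV
#'
#' @param x A `flops_ledger` from [count_flops()].
#' @param path Output CSV path.
#' @export
write_flops_csv <- function(x, path) {
  stopifnot(inherits(x, "flops_ledger"))
  utils::write.csv(x$ledger, path, row.names = FALSE)
  invisible(path)
}

#' Save / load model checkpoints
#'
#' Checkpoints carry the configuration, all trainable weights and the batch
#' normalisation running statistics, so a reloaded model reproduces the
#' saved model's inference outputs exactly.
#'
#' @param model A `psp_model`.
#' @param path Checkpoint file path (`.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "psp_model"))
  saveRDS(list(config = model$config,
               weights = net_get_weights(model$net),
               bn = net_collect_bn(model$net$bns)),
          path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `psp_model`.
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- suppressWarnings(build_model(ck$config))
  net_set_weights(model$net, ck$weights)
  net_restore_bn(model$net$bns, ck$bn)
  model
}
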