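# Training recipe and evaluation harness: Adam on the combined
# BCE + Dice loss, learning-rate reduction on validation-Dice plateau,
# early stopping, best-weight restoration, and multi-seed summaries.

#' Loss configuration
#'
#' @param lambda_bce,lambda_dice Non-negative weights of the binary
#'   cross-entropy and Dice terms (defaults 0.5 each).
#' @param dice_smooth Smoothing constant added to the Dice numerator and
#'   denominator so empty masks are well-behaved.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(lambda_bce = 0.5, lambda_dice = 0.5, dice_smooth = 1e-6) {
  if (lambda_bce < 0 || lambda_dice < 0 || lambda_bce + lambda_dice <= 0)
    stop("loss weights must be non-negative with a positive sum")
  structure(list(lambda_bce = lambda_bce, lambda_dice = lambda_dice,
                 dice_smooth = dice_smooth), class = "loss_config")
}

#' Combined BCE + Dice loss
#'
#' `lambda_bce * BCE(pred, gt) + lambda_dice * (1 - (2 sum(p g) + eps) /
#' (sum(p) + sum(g) + eps))` with BCE averaged over pixels.  Probabilities
#' are clipped away from 0 and 1 for numerical stability.
#'
#' @param pred Probability array in (0, 1).
#' @param gt Binary array of the same shape.
#' @param config A [loss_config()].
#' @return Non-negative scalar.
#' @export
combined_loss <- function(pred, gt, config = loss_config()) {
  if (!identical(dim(pred), dim(gt)) && length(pred) != length(gt))
    stop("pred/gt shape mismatch")
  check_binary(gt, "gt")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)   # clip only inside the logs
  bce <- -mean(gt * log(p) + (1 - gt) * log(1 - p))
  eps <- config$dice_smooth
  dice <- (2 * sum(pred * gt) + eps) / (sum(pred) + sum(gt) + eps)
  config$lambda_bce * bce + config$lambda_dice * (1 - dice)
}

# Batch loss and its gradient w.r.t. the probability map.  Dice is computed
# per sample and averaged, BCE over all pixels.
batch_loss_grad <- function(pred, gt, config) {
  n <- dim(pred)[4]
  npx <- length(pred)
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  bce <- -mean(gt * log(p) + (1 - gt) * log(1 - p))
  g_bce <- (p - gt) / (p * (1 - p)) / npx
  eps <- config$dice_smooth
  dice_terms <- numeric(n)
  g_dice <- array(0, dim(pred))
  for (i in seq_len(n)) {
    pi <- p[, , , i]; gi <- gt[, , , i]
    num <- 2 * sum(pi * gi) + eps
    den <- sum(pi) + sum(gi) + eps
    dice_terms[i] <- num / den
    g_dice[, , , i] <- -(2 * gi * den - num) / den^2 / n
  }
  loss <- config$lambda_bce * bce + config$lambda_dice * (1 - mean(dice_terms))
  grad <- config$lambda_bce * g_bce + config$lambda_dice * g_dice
  list(loss = loss, grad = grad)
}

#' Training configuration
#'
#' Defaults follow the training recipe: Adam with initial learning rate
#' 2e-4, batch size 16, at most 25 epochs, learning rate halved after 6
#' epochs without validation-Dice improvement (floor 1e-7), early stopping
#' after 12 stagnant epochs, best weights chosen by highest validation
#' Dice, inference threshold 0.5, and repeat seeds 42, 21, 7.
#'
#' @param learning_rate,batch_size,max_epochs Optimiser basics.
#' @param lr_factor,lr_patience,lr_min Plateau schedule.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param min_delta Minimum validation-Dice increase counted as improvement.
#' @param threshold Sigmoid threshold for binarising predictions.
#' @param seeds Seeds for repeated runs.
#' @param loss A [loss_config()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, batch_size = 16L,
                         max_epochs = 25L, lr_factor = 0.5, lr_patience = 6L,
                         lr_min = 1e-7, early_stop_patience = 12L,
                         min_delta = 1e-4, threshold = 0.5,
                         seeds = c(42L, 21L, 7L), loss = loss_config()) {
  stopifnot(lr_factor > 0, lr_factor < 1, lr_min < learning_rate,
            lr_patience >= 1, early_stop_patience >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), lr_min = lr_min,
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, threshold = threshold,
                 seeds = as.integer(seeds), loss = loss),
            class = "train_config")
}

# Plateau scheduler / early-stopping state machine.  `improvement` means a
# strict increase of the monitored metric beyond min_delta; the stagnation
# counters are shared between LR reduction and early stopping.
sched_init <- function(cfg) {
  list(lr = cfg$learning_rate, best = -Inf, best_epoch = 0L,
       lr_wait = 0L, stop_wait = 0L, stop = FALSE, improved = FALSE)
}

sched_step <- function(state, metric, epoch, cfg) {
  if (metric > state$best + cfg$min_delta) {
    state$best <- metric
    state$best_epoch <- epoch
    state$lr_wait <- 0L
    state$stop_wait <- 0L
    state$improved <- TRUE
  } else {
    state$improved <- FALSE
    state$lr_wait <- state$lr_wait + 1L
    state$stop_wait <- state$stop_wait + 1L
    if (state$lr_wait >= cfg$lr_patience) {
      state$lr <- max(state$lr * cfg$lr_factor, cfg$lr_min)
      state$lr_wait <- 0L
    }
    if (state$stop_wait >= cfg$early_stop_patience) state$stop <- TRUE
  }
  state
}

# Fused in-place Adam update (the C++ kernel mutates p$v/p$m/p$s, which the
# parameter environments own exclusively; checkpoint accessors copy).
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (p in params) {
    if (is.null(p$g)) next
    if (is.null(p$m)) {
      p$m <- 0 * p$v
      p$s <- 0 * p$v
    }
    cpp_adam_step(p$v, p$g, p$m, p$s, lr, beta1, beta2, eps, b1t, b2t)
  }
  invisible(NULL)
}

stack_batch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$image)
  x <- array(0, c(d[1], d[2], 3L, length(idx)))
  g <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- samples[[idx[j]]]$image
    g[, , 1, j] <- samples[[idx[j]]]$mask
  }
  list(x = x, g = g)
}

# Mean thresholded Dice over samples, in inference mode.
validation_dice <- function(model, samples, threshold, batch_size = 8L) {
  dices <- numeric(length(samples))
  i <- 1L
  while (i <= length(samples)) {
    idx <- i:min(i + batch_size - 1L, length(samples))
    b <- stack_batch(samples, idx)
    p <- model_forward_t(model, ag_tensor(b$x), training = FALSE)$v
    for (j in seq_along(idx)) {
      pb <- (p[, , 1, j] >= threshold) * 1
      dices[idx[j]] <- overlap_metrics(pb, b$g[, , 1, j])$dice
    }
    i <- i + batch_size
  }
  mean(dices)
}

#' Train a segmentation model
#'
#' Optimises the combined BCE + Dice loss with Adam.  After every epoch the
#' thresholded Dice on the validation samples is monitored: the learning
#' rate is multiplied by `lr_factor` after `lr_patience` epochs without
#' improvement (never below `lr_min`), training stops after
#' `early_stop_patience` stagnant epochs or at `max_epochs`, and the
#' weights of the best validation epoch are restored into the model.
#'
#' @param model A `psp_model` (modified in place).
#' @param train_samples,val_samples Non-empty lists of `slice_sample`s at
#'   the model's input size.
#' @param config A [train_config()].
#' @param seed Seed controlling batch shuffling (weights were seeded at
#'   build time).
#' @param verbose Print one line per epoch.
#' @return A list of class `train_history`: `history` data frame (epoch,
#'   loss, val_dice, lr), `best_val_dice`, `best_epoch`.
#' @export
train_model <- function(model, train_samples, val_samples,
                        config = train_config(), seed = 42L, verbose = FALSE) {
  stopifnot(inherits(model, "psp_model"), inherits(config, "train_config"))
  if (length(train_samples) == 0L || length(val_samples) == 0L)
    stop("train and validation sample lists must be non-empty")
  params <- model$net$params
  state <- sched_init(config)
  best_weights <- NULL
  best_bn <- NULL
  hist <- list()
  t_adam <- 0L
  withr_seed(seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(train_samples))
      losses <- c()
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        b <- stack_batch(train_samples, idx)
        out <- model_forward_t(model, ag_tensor(b$x), training = TRUE)
        lg <- batch_loss_grad(out$v, b$g, config$loss)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch,
               " (batch starting at sample ", i, ")")
        ag_backward(out, lg$grad)
        t_adam <- t_adam + 1L
        adam_step(params, state$lr, t_adam)
        ag_zero_grads(params)
        losses <- c(losses, lg$loss)
        i <- i + config$batch_size
      }
      vd <- validation_dice(model, val_samples, config$threshold)
      lr_at_epoch <- state$lr
      state <- sched_step(state, vd, epoch, config)
      if (state$improved) {
        best_weights <- net_get_weights(model$net)
        best_bn <- net_collect_bn(model$net$bns)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                  val_dice = vd, lr = lr_at_epoch)
      if (verbose)
        message(sprintf("epoch %d loss %.4f val_dice %.4f lr %.2e",
                        epoch, mean(losses), vd, lr_at_epoch))
      if (state$stop) break
    }
  })
  if (!is.null(best_weights)) {
    net_set_weights(model$net, best_weights)
    net_restore_bn(model$net$bns, best_bn)
  }
  structure(list(history = do.call(rbind, hist),
                 best_val_dice = state$best, best_epoch = state$best_epoch),
            class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history> %d epochs, best val dice %.4f at epoch %d\n",
              nrow(x$history), x$best_val_dice, x$best_epoch))
  invisible(x)
}

#' Evaluate a model on whole volumes
#'
#' Every slice of every volume is preprocessed, predicted, thresholded and
#' scored; per-slice records and slice-/patient-level summaries are
#' returned.  Background-only slices are included (the both-empty overlap
#' convention gives them IoU = Dice = 1 when predicted empty); set
#' `overlap_slices = "liver_only"` to restrict overlap aggregation to
#' slices whose reference mask contains liver.
#'
#' @param model A `psp_model`.
#' @param volumes List of `volume_record`s.
#' @param threshold Binarisation threshold (default 0.5).
#' @param overlap_slices `"all"` or `"liver_only"`.
#' @param batch_size Inference batch size.
#' @return List: `records` (per slice), `slice_summary`, `patient_summary`.
#' @export
evaluate_model <- function(model, volumes, threshold = 0.5,
                           overlap_slices = c("all", "liver_only"),
                           batch_size = 8L) {
  overlap_slices <- match.arg(overlap_slices)
  size <- model$config$input_size
  recs <- list()
  for (vol in volumes) {
    samples <- lapply(seq_along(vol$slices), function(k)
      make_slice_sample(vol, k, size))
    i <- 1L
    while (i <= length(samples)) {
      idx <- i:min(i + batch_size - 1L, length(samples))
      b <- stack_batch(samples, idx)
      p <- model_forward_t(model, ag_tensor(b$x), training = FALSE)$v
      for (j in seq_along(idx)) {
        pb <- (p[, , 1, j] >= threshold) * 1
        recs[[length(recs) + 1L]] <-
          slice_metrics(pb, b$g[, , 1, j], vol$patient_id, idx[j])
      }
      i <- i + batch_size
    }
  }
  records <- do.call(rbind, recs)
  if (overlap_slices == "liver_only") {
    has_liver <- unlist(lapply(volumes, function(vol)
      vapply(vol$masks, function(m) any(m > 0), logical(1))))
    records <- records[has_liver, , drop = FALSE]
  }
  list(records = records,
       slice_summary = aggregate_metrics(records, "slice"),
       patient_summary = aggregate_metrics(records, "patient"))
}

#' Repeat training over several seeds
#'
#' Builds, trains and evaluates one model per seed and reports per-seed
#' results plus the cross-seed mean and standard deviation of every test
#' metric (standard deviations require at least two seeds).
#'
#' @param base_config A [model_config()]; its `seed` field is replaced by
#'   each run's seed.
#' @param train_samples,val_samples Training inputs.
#' @param test_volumes Volumes for final evaluation.
#' @param config A [train_config()]; `config$seeds` drives the runs.
#' @return A list of class `run_summary`: `per_seed` (list of histories and
#'   summaries) and `summary` (metric, mean, sd over seeds at patient
#'   level).
#' @export
train_multiseed <- function(base_config, train_samples, val_samples,
                            test_volumes, config = train_config()) {
  per_seed <- list()
  for (sd_i in config$seeds) {
    cfg <- base_config
    cfg$seed <- sd_i
    model <- build_model(cfg)
    hist <- train_model(model, train_samples, val_samples, config, seed = sd_i)
    ev <- evaluate_model(model, test_volumes, config$threshold)
    per_seed[[as.character(sd_i)]] <-
      list(seed = sd_i, best_val_dice = hist$best_val_dice,
           best_epoch = hist$best_epoch, patient_summary = ev$patient_summary)
  }
  metrics <- c("iou", "dice", "hd95", "assd")
  rows <- lapply(metrics, function(m) {
    v <- vapply(per_seed, function(r)
      r$patient_summary$mean[r$patient_summary$metric == m], numeric(1))
    v <- v[!is.na(v)]
    data.frame(metric = m, mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n_seeds = length(v), stringsAsFactors = FALSE)
  })
  structure(list(per_seed = per_seed, summary = do.call(rbind, rows)),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> %d seeds; patient-level test metrics:\n",
              length(x$per_seed)))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-5s %.4f +/- %s\n", x$summary$metric[i], x$summary$mean[i],
                ifelse(is.na(x$summary$sd[i]), "NA",
                       sprintf("%.4f", x$summary$sd[i]))))
  invisible(x)
}
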