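# Combined loss, gradients, the plateau/early-stop recipe and the
# training harness on miniature problems.

test_that("combined loss obeys its closed-form anchors", {
  g <- matrix(c(1, 0, 0, 1), 2, 2)
  near <- pmin(pmax(g, 1e-7), 1 - 1e-7)
  expect_lt(combined_loss(near, g), 1e-5)              # perfect prediction
  # empty reference, near-zero prediction: both terms vanish by smoothing
  z <- matrix(0, 4, 4)
  expect_lt(combined_loss(matrix(1e-10, 4, 4), z), 2e-3)
  # uniform 0.5: the BCE component is exactly ln 2
  cfg_bce <- loss_config(lambda_bce = 1, lambda_dice = 0)
  for (gt in list(z, g)) {
    p <- matrix(0.5, nrow(gt), ncol(gt))
    expect_equal(combined_loss(p, gt, cfg_bce), log(2), tolerance = 1e-12)
  }
  expect_error(loss_config(lambda_bce = -1), "non-negative")
})

test_that("loss decreases monotonically from uniform 0.5 toward the target", {
  set.seed(41)
  g <- random_mask(16)
  losses <- vapply(seq(0, 1, by = 0.1), function(t) {
    p <- pmin(pmax((1 - t) * 0.5 + t * g, 1e-6), 1 - 1e-6)
    combined_loss(p, g)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("the batch loss gradient matches finite differences", {
  set.seed(42)
  p <- array(runif(6 * 6 * 1 * 2, 0.2, 0.8), c(6, 6, 1, 2))
  g <- array((array(runif(72), c(6, 6, 1, 2)) > 0.5) * 1, c(6, 6, 1, 2))
  lc <- loss_config()
  lg <- pspmsff:::batch_loss_grad(p, g, lc)
  f <- function(pv) pspmsff:::batch_loss_grad(pv, g, lc)$loss
  eps <- 1e-6
  for (k in sample(length(p), 6)) {
    pp <- p; pp[k] <- pp[k] + eps
    pm <- p; pm[k] <- pm[k] - eps
    expect_equal(lg$grad[k], (f(pp) - f(pm)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("learning rate halves after 6 stagnant epochs, floors at 1e-7, stops at 12", {
  cfg <- train_config()
  st <- pspmsff:::sched_init(cfg)
  st <- pspmsff:::sched_step(st, 0.5, 1L, cfg)     # improvement
  expect_equal(st$lr, 2e-4)
  for (e in 2:7) st <- pspmsff:::sched_step(st, 0.5, e, cfg)  # 6 stagnant
  expect_equal(st$lr, 1e-4)                        # 2e-4 -> 1e-4
  expect_false(st$stop)
  for (e in 8:13) st <- pspmsff:::sched_step(st, 0.5, e, cfg)
  expect_equal(st$lr, 5e-5)
  expect_true(st$stop)                             # 12 stagnant epochs
  expect_equal(st$best_epoch, 1L)
  # floor: repeated halvings never drop below 1e-7
  st2 <- pspmsff:::sched_init(cfg)
  for (e in 1:200) st2 <- pspmsff:::sched_step(st2, 0.1, e, cfg)
  expect_equal(st2$lr, 1e-7)
  # min-delta: a sub-threshold increase is not an improvement
  st3 <- pspmsff:::sched_init(cfg)
  st3 <- pspmsff:::sched_step(st3, 0.5, 1L, cfg)
  st3 <- pspmsff:::sched_step(st3, 0.5 + 5e-5, 2L, cfg)
  expect_false(st3$improved)
})

test_that("every parameter receives a nonzero gradient in one optimisation step", {
  # run at 64^2 so no feature map degenerates to 1x1, where a downstream
  # batch norm makes the preceding shift gradient exactly zero by identity
  set.seed(44)
  m <- tiny_model(input_size = 64L)
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  g <- array((array(rnorm(64 * 64 * 2), c(64, 64, 1, 2)) > 0) * 1,
             c(64, 64, 1, 2))
  out <- pspmsff:::model_forward_t(m, pspmsff:::ag_tensor(x), training = TRUE)
  lg <- pspmsff:::batch_loss_grad(out$v, g, loss_config())
  pspmsff:::ag_backward(out, lg$grad)
  has_grad <- vapply(m$net$params, function(p) !is.null(p$g), logical(1))
  expect_true(all(has_grad))
  nonzero <- vapply(m$net$params, function(p) any(p$g != 0), logical(1))
  # full trainability: branch, attention, projection and encoder weights
  # all receive signal
  expect_true(all(nonzero))
})

test_that("training improves a tiny model deterministically with a sane LR trace", {
  samples <- tiny_samples(n = 4L, size = 32L)
  cfg <- train_config(batch_size = 2L, max_epochs = 3L)
  m1 <- tiny_model(input_size = 32L, seed = 5L)
  h1 <- train_model(m1, samples, samples, cfg, seed = 5)
  m2 <- tiny_model(input_size = 32L, seed = 5L)
  h2 <- train_model(m2, samples, samples, cfg, seed = 5)
  expect_identical(h1$history$loss[1], h2$history$loss[1])   # determinism
  expect_equal(h1$history$loss, h2$history$loss)
  expect_lt(tail(h1$history$loss, 1), h1$history$loss[1])    # learning
  expect_true(all(diff(h1$history$lr) <= 0))                 # non-increasing
  expect_true(all(h1$history$lr >= 1e-7))
  expect_named(h1$history, c("epoch", "loss", "val_dice", "lr"))
  expect_error(train_model(m1, list(), samples, cfg), "non-empty")
})

test_that("restored best weights reproduce the logged best validation Dice", {
  samples <- tiny_samples(n = 4L, size = 32L, seed = 10L)
  m <- tiny_model(input_size = 32L, seed = 6L)
  h <- train_model(m, samples, samples,
                   train_config(batch_size = 4L, max_epochs = 3L), seed = 6)
  vd <- pspmsff:::validation_dice(m, samples, 0.5)
  expect_equal(vd, h$best_val_dice, tolerance = 1e-12)
})

test_that("non-finite losses abort with a diagnostic", {
  samples <- tiny_samples(n = 2L, size = 32L)
  m <- tiny_model(input_size = 32L)
  # corrupt one image so the forward pass produces NaN
  samples[[1]]$image[1] <- NaN
  expect_error(
    train_model(m, samples, samples,
                train_config(batch_size = 2L, max_epochs = 1L)),
    "non-finite")
})

test_that("multi-seed runs report mean and spread across seeds", {
  spec <- phantom_spec(n_patients = 3, slices_per_patient = 2, image_size = 64,
                       background_slice_fraction = 0, seed = 11)
  vols <- lapply(1:3, function(i) make_phantom_volume(spec, i))
  samples <- phantom_samples(vols[1:2], size = 32)
  rs <- suppressWarnings(   # reduced-input build drops oversized pyramid bins
    train_multiseed(model_config(input_size = 32L),
                    samples, samples, vols[3],
                    train_config(batch_size = 4L, max_epochs = 1L,
                                 seeds = c(42L, 21L))))
  expect_s3_class(rs, "run_summary")
  expect_length(rs$per_seed, 2L)
  expect_equal(rs$summary$n_seeds[rs$summary$metric == "dice"], 2L)
  expect_false(is.na(rs$summary$sd[rs$summary$metric == "dice"]))
})
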