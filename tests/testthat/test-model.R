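# Whole-model assembly, variants, forward contract, FLOPs ledger,
# checkpointing.

test_that("decoder stages follow the published channel schedule and skip order", {
  m <- tiny_model(input_size = 64L, variant = "full_msff")
  led <- count_flops(m)$ledger
  dec <- led[grepl("^dec_stage", led$layer), ]
  expect_equal(dec$c_out, c(512L, 256L, 128L, 64L, 32L))
  # stage i consumes skip (5 - i): refine input channels = prev + skip
  expect_equal(dec$c_in, c(512L + 672L, 512L + 240L, 256L + 144L,
                           128L + 96L, 64L))
  expect_equal(dec$h_out, c(4L, 8L, 16L, 32L, 64L))   # doubling 2 -> 64
  head <- led[led$layer == "head", ]
  expect_equal(c(head$c_in, head$c_out, head$h_out), c(32L, 1L, 64L))
})

test_that("ablation variants change only the skip wiring", {
  skip <- tiny_model(input_size = 64L, variant = "skip_only")
  none <- tiny_model(input_size = 64L, variant = "no_skip")
  ls <- count_flops(skip)$ledger
  ln <- count_flops(none)$ledger
  expect_false(any(grepl("msff", ls$layer)))
  dn <- ln[grepl("^dec_stage", ln$layer), ]
  expect_equal(dn$c_in, c(512L, 512L, 256L, 128L, 64L))  # no concatenation
  expect_equal(dn$h_out, c(4L, 8L, 16L, 32L, 64L))       # same resolutions
  # shared layers (encoder + PPM + head) match line by line
  shared <- intersect(ls$layer, ln$layer)
  shared <- setdiff(shared, ls$layer[grepl("^dec_stage", ls$layer)])
  expect_equal(ls$flops[match(shared, ls$layer)],
               ln$flops[match(shared, ln$layer)])
})

test_that("forward yields probabilities of the input size, bitwise repeatable", {
  m <- tiny_model(input_size = 64L)
  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  p1 <- predict(m, x)
  expect_equal(dim(p1), c(64L, 64L, 1L, 2L))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, predict(m, x))
  expect_error(predict(m, array(0, c(32, 32, 3))), "built for")
})

test_that("FLOPs follow the stated convention and the ledger is additive", {
  # single convolutions evaluated directly from the formula
  net <- pspmsff:::new_net()
  pspmsff:::new_conv(net, "c1", 3L, 3L, 3L, 8L, c(4L, 4L), pad = c(1L, 1L, 1L, 1L))
  pspmsff:::new_conv(net, "c2", 1L, 1L, 1280L, 512L, c(8L, 8L))
  fake <- structure(list(net = net), class = "psp_encoder")
  led <- count_flops(fake)$ledger
  expect_equal(led$flops[led$layer == "c1"], 2 * 3 * 9 * 8 * 16)        # 6912
  expect_equal(led$flops[led$layer == "c2"], 2 * 1280 * 512 * 64)       # 83886080
  m <- tiny_model(input_size = 64L)
  fl <- count_flops(m)
  expect_equal(fl$total, sum(fl$ledger$flops))
  expect_equal(fl$gflops, fl$total / 1e9)
  # removing MSFF changes only MSFF-attributed entries
  ls <- count_flops(tiny_model(input_size = 64L, variant = "skip_only"))$ledger
  lf <- fl$ledger
  common <- intersect(lf$layer, ls$layer)
  expect_equal(lf$flops[match(common, lf$layer)],
               ls$flops[match(common, ls$layer)])
  expect_true(all(grepl("msff", setdiff(lf$layer, ls$layer))))
})

test_that("the ledger matches an independent closed-form recomputation", {
  for (variant in c("full_msff", "skip_only", "no_skip")) {
    got <- count_flops(tiny_model(input_size = 256L, variant = variant))$total
    want <- oracle_flops(variant, 256)
    expect_lt(abs(got - want) / want, 0.02)
  }
})

test_that("checkpoints restore weights, BN statistics and predictions exactly", {
  m <- tiny_model(input_size = 32L)
  # perturb BN running stats so the round trip is non-trivial
  for (b in m$net$bns) b$rmean <- b$rmean + 0.1
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  p1 <- predict(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, x), p1, tolerance = 1e-12)
})

test_that("FLOPs ledger exports to CSV", {
  fl <- count_flops(tiny_model(input_size = 32L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_flops_csv(fl, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(fl$ledger))
  expect_equal(sum(back$flops), fl$total)
})

test_that("decoder channel schedule is validated", {
  expect_error(model_config(decoder_channels = c(512, 256, 128, 64)),
               "5 strictly decreasing")
  expect_error(model_config(decoder_channels = c(512, 256, 256, 64, 32)),
               "strictly decreasing")
})
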