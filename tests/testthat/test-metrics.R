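# Overlap metrics, surface distances and aggregation.

test_that("overlap metrics follow the confusion-count definitions", {
  m <- matrix(0, 8, 8); m[2:5, 2:5] <- 1
  expect_equal(overlap_metrics(m, m), list(iou = 1, dice = 1))
  d <- matrix(0, 8, 8); d[7:8, 7:8] <- 1
  expect_equal(overlap_metrics(m, d), list(iou = 0, dice = 0))
  # TP=2, FP=1, FN=1 -> IoU = 1/2, Dice = 2/3
  pred <- matrix(0, 4, 4); pred[1, 1:3] <- 1
  gt <- matrix(0, 4, 4); gt[1, 2:4] <- 1
  expect_equal(overlap_metrics(pred, gt), list(iou = 0.5, dice = 2 / 3))
  cc <- confusion_counts(pred, gt)
  expect_equal(cc[c("TP", "FP", "FN")], list(TP = 2L, FP = 1L, FN = 1L))
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 16L)
  # both empty -> perfect by convention
  z <- matrix(0, 5, 5)
  expect_equal(overlap_metrics(z, z), list(iou = 1, dice = 1))
  expect_error(overlap_metrics(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("Dice = 2 IoU / (1 + IoU) on random mask pairs", {
  set.seed(31)
  for (i in 1:50) {
    a <- random_mask(24); b <- random_mask(24)
    ov <- overlap_metrics(a, b)
    expect_equal(ov$dice, 2 * ov$iou / (1 + ov$iou), tolerance = 1e-12)
  }
})

test_that("surface distances satisfy identity, symmetry and scaling", {
  m <- matrix(0, 16, 16); m[4:9, 5:12] <- 1
  sd0 <- surface_distances(m, m)
  expect_equal(sd0$hd95, 0)
  expect_equal(sd0$assd, 0)
  # single pixels 5 apart along a row
  a <- matrix(0, 12, 12); a[6, 2] <- 1
  b <- matrix(0, 12, 12); b[6, 7] <- 1
  sdp <- surface_distances(a, b)
  expect_equal(sdp$hd95, 5)
  expect_equal(sdp$assd, 5)
  # symmetry
  set.seed(32)
  x <- random_mask(24); y <- random_mask(24)
  s1 <- surface_distances(x, y); s2 <- surface_distances(y, x)
  expect_equal(s1$hd95, s2$hd95)
  expect_equal(s1$assd, s2$assd)
  # linear scaling under integer dilation of coordinates
  a2 <- matrix(0, 24, 24); a2[12, 4] <- 1
  b2 <- matrix(0, 24, 24); b2[12, 14] <- 1
  sdl <- surface_distances(a2, b2)
  expect_equal(sdl$hd95, 2 * sdp$hd95)
  expect_equal(sdl$assd, 2 * sdp$assd)
  # empty mask -> invalid result, not an exception
  e <- surface_distances(matrix(0, 8, 8), m[1:8, 1:8])
  expect_false(e$valid)
  expect_true(is.na(e$hd95) && is.na(e$assd))
})

test_that("surface distances equal the brute-force all-pairs oracle", {
  set.seed(33)
  for (i in 1:40) {
    a <- random_mask(32); b <- random_mask(32)
    if (!any(a == 1) || !any(b == 1)) next
    got <- surface_distances(a, b)
    want <- brute_surface_distances(a, b)
    expect_equal(got$hd95, want$hd95, tolerance = 1e-9)
    expect_equal(got$assd, want$assd, tolerance = 1e-9)
    expect_lte(got$hd95, want$hd + 1e-12)   # percentile <= max Hausdorff
  }
})

test_that("boundaries are foreground pixels with a background 4-neighbour", {
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  bp <- boundary_points(m)
  expect_equal(nrow(bp), 12L)              # 4x4 block: all but the 2x2 core
  expect_true(all(m[bp] == 1))
  full <- matrix(1, 4, 4)                  # image border counts as background
  expect_equal(nrow(boundary_points(full)), 12L)
})

test_that("aggregation distinguishes slice and patient level", {
  recs <- rbind(
    slice_metrics(matrix(1, 4, 4), matrix(1, 4, 4), "A", 1L),
    do.call(rbind, lapply(1:9, function(k) {
      p <- matrix(0, 4, 4); p[1:2, 1:2] <- 1
      g <- matrix(0, 4, 4); g[1:2, 1:4] <- 1   # dice = 2*4/(4+8) = 2/3
      slice_metrics(p, g, "B", k)
    })))
  recs$dice <- c(1, rep(0.5, 9))               # construct the worked example
  sl <- aggregate_metrics(recs, "slice")
  pa <- aggregate_metrics(recs, "patient")
  expect_equal(sl$mean[sl$metric == "dice"], 0.55)
  expect_equal(pa$mean[pa$metric == "dice"], 0.75)
  # identical slices of one patient: mean equals the value, sd 0
  one <- do.call(rbind, lapply(1:3, function(k)
    slice_metrics(matrix(1, 4, 4), matrix(1, 4, 4), "A", k)))
  s <- aggregate_metrics(one, "patient")
  expect_equal(s$mean[s$metric == "dice"], 1)
  expect_equal(s$sd[s$metric == "iou"], NA_real_)  # single patient
  # no valid distance records: overlap present, distances flagged absent
  z <- matrix(0, 4, 4)
  empty <- rbind(slice_metrics(z, z, "A", 1L), slice_metrics(z, z, "A", 2L))
  s2 <- aggregate_metrics(empty, "slice")
  expect_equal(s2$n[s2$metric == "hd95"], 0L)
  expect_true(is.na(s2$mean[s2$metric == "assd"]))
  expect_equal(s2$mean[s2$metric == "dice"], 1)
})

test_that("metrics CSV includes per-slice rows and summary rows", {
  recs <- rbind(slice_metrics(matrix(1, 4, 4), matrix(1, 4, 4), "A", 1L),
                slice_metrics(matrix(0, 4, 4), matrix(0, 4, 4), "A", 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(recs, path)
  out <- read.csv(path)
  expect_equal(nrow(out), 4L)   # 2 slices + slice & patient summaries
  expect_true(any(grepl("__summary_slice__", out$patient_id)))
})
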