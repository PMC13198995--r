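# Preprocessing, patient-level splitting, slice sampling and volume IO.

test_that("preprocess_image applies the affine [0,255] -> [-1,1] map", {
  expect_equal(preprocess_image(matrix(127.5, 64, 64), size = 64),
               array(0, c(64, 64, 3)))
  expect_equal(preprocess_image(matrix(0, 64, 64), size = 64),
               array(-1, c(64, 64, 3)))
  expect_equal(preprocess_image(matrix(255, 64, 64), size = 64),
               array(1, c(64, 64, 3)))
  out <- preprocess_image(matrix(runif(512 * 512, 0, 255), 512, 512))
  expect_equal(dim(out), c(256L, 256L, 3L))
  expect_true(all(out >= -1 & out <= 1))
  expect_identical(out[, , 1], out[, , 2])
  expect_identical(out[, , 1], out[, , 3])
  expect_error(preprocess_image(matrix(c(NA, 1:63), 8, 8)), "non-finite")
  # out-of-nominal-range inputs are min-max rescaled first
  raw <- matrix(rnorm(64^2, mean = 1000, sd = 300), 64, 64)
  out2 <- preprocess_image(raw, size = 64)
  expect_true(all(is.finite(out2)) && all(out2 >= -1 & out2 <= 1))
  expect_equal(min(out2), -1)
  expect_equal(max(out2), 1)
})

test_that("preprocess_mask binarizes positive labels and preserves area under resize", {
  m <- matrix(0, 64, 64)
  m[10:20, 30:40] <- 2
  m[50:60, 5:10] <- 7
  out <- preprocess_mask(m, size = 64)
  expect_true(all(out %in% c(0, 1)))
  expect_equal(sum(out), sum(m > 0))
  expect_equal(preprocess_mask(matrix(0, 40, 40), size = 256),
               matrix(0, 256, 256))
  # a 100x100 disk upsized to 256x256 scales in area by ~ (256/100)^2
  disk <- matrix(0, 100, 100)
  xs <- matrix(1:100, 100, 100); ys <- t(xs)
  disk[(xs - 50)^2 + (ys - 50)^2 <= 30^2] <- 1
  up <- preprocess_mask(disk, size = 256)
  expect_equal(sum(up) / sum(disk), (256 / 100)^2, tolerance = 0.02)
})

test_that("split_patients reproduces the published cohort splits exactly", {
  for (cs in list(list(n = 95, sizes = c(66, 10, 19)),
                  list(n = 318, sizes = c(222, 32, 64)),
                  list(n = 10, sizes = c(7, 1, 2)))) {
    sp <- split_patients(sprintf("p%03d", seq_len(cs$n)), seed = 1)
    expect_equal(c(length(sp$train_ids), length(sp$val_ids),
                   length(sp$test_ids)), cs$sizes)
  }
  expect_error(split_patients(c("a", "b")), "at least 3")
  expect_error(split_patients(c("a", "b", "b", "c")), "unique")
})

test_that("split_patients partitions the cohort for any size and seed", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(3:400, 1)
    ids <- sprintf("pat%04d", seq_len(n))
    sp <- split_patients(ids, seed = sample.int(1e6, 1))
    all_assigned <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_equal(sort(all_assigned), sort(ids))         # coverage
    expect_equal(anyDuplicated(all_assigned), 0L)       # disjointness
    expect_equal(length(sp$train_ids), floor(0.7 * n))
    expect_equal(length(sp$test_ids), floor(0.2 * n + 0.5))
  }
  # same seed -> same split; different seed -> (almost surely) different
  s1 <- split_patients(sprintf("p%d", 1:50), seed = 5)
  s2 <- split_patients(sprintf("p%d", 1:50), seed = 5)
  expect_identical(s1$train_ids, s2$train_ids)
})

test_that("sample_slices is deterministic, ascending and endpoint-preserving", {
  expect_equal(sample_slices(20L, 50L), 1:20)
  expect_equal(sample_slices(5L, 2L), c(1L, 5L))
  idx <- sample_slices(100L, 50L)
  expect_length(idx, 50L)
  expect_equal(idx[1], 1L)
  expect_equal(idx[length(idx)], 100L)
  expect_true(all(diff(idx) > 0))
  for (i in 1:20) {
    s <- sample(1:200, 1); mx <- sample(1:60, 1)
    idx <- sample_slices(s, mx)
    expect_true(all(diff(idx) > 0))
    expect_lte(length(idx), min(s, mx))
    expect_identical(idx, sample_slices(s, mx))   # no randomness
  }
  expect_error(sample_slices(0L, 5L), "no slices")
})

test_that("NIfTI volumes round-trip pixel-identically through write and read", {
  spec <- phantom_spec(n_patients = 2, slices_per_patient = 5, image_size = 64,
                       seed = 3)
  dir <- withr::local_tempdir()
  ds <- make_phantom_dataset(spec, dir, format = "nifti")
  vol <- read_slice_stack(ds$manifest$image_path[1], "nifti_volume",
                          mask_path = ds$manifest$mask_path[1])
  expect_length(vol$slices, 5L)
  expect_length(vol$masks, 5L)
  for (k in 1:5) {
    expect_equal(vol$slices[[k]], ds$volumes[[1]]$slices[[k]],
                 ignore_attr = TRUE, tolerance = 1e-6)
    expect_equal(vol$masks[[k]], ds$volumes[[1]]$masks[[k]],
                 ignore_attr = TRUE)
  }
  expect_error(read_slice_stack(ds$manifest$image_path[1], "nifti_volume"),
               "mask_path")
})

test_that("image directories pair by stem and report orphans", {
  spec <- phantom_spec(n_patients = 1, slices_per_patient = 3, image_size = 64,
                       seed = 4)
  dir <- withr::local_tempdir()
  ds <- make_phantom_dataset(spec, dir, format = "png")
  pdir <- ds$manifest$image_path[1]
  vol <- read_slice_stack(pdir, "image_directory")
  expect_length(vol$slices, 3L)
  expect_true(all(vol$masks[[2]] %in% c(0, 1)))
  # 8-bit PNG quantisation: intensities within half a grey level
  expect_lt(max(abs(vol$slices[[1]] - ds$volumes[[1]]$slices[[1]])), 0.51)
  file.remove(file.path(pdir, "slice002_mask.png"))
  expect_error(read_slice_stack(pdir, "image_directory"), "slice002")
})

test_that("split manifests round-trip through CSV", {
  sp <- split_patients(sprintf("p%d", 1:12), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(sp, path)
  man <- read_split_manifest(path)
  expect_equal(nrow(man), 12L)
  expect_setequal(man$patient_id[man$subset == "train"], sp$train_ids)
  expect_setequal(man$patient_id[man$subset == "test"], sp$test_ids)
})

test_that("slice samples carry identity and the preprocessing provenance flag", {
  spec <- phantom_spec(n_patients = 1, slices_per_patient = 4, image_size = 64,
                       seed = 5)
  vol <- make_phantom_volume(spec, 1)
  s <- make_slice_sample(vol, 2, size = 64)
  expect_s3_class(s, "slice_sample")
  expect_true(s$preprocessed)          # the affine map is applied exactly once
  expect_equal(s$patient_id, vol$patient_id)
  expect_equal(s$slice_index, 2L)
  expect_true(all(s$image >= -1 & s$image <= 1))
  expect_true(all(s$mask %in% c(0, 1)))
})
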