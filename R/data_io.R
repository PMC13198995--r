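# Reading slice stacks, preprocessing, patient-level splitting and
# per-patient uniform slice sampling.

new_volume_record <- function(patient_id, slices, masks, modality_tag = "") {
  if (length(slices) != length(masks) || length(slices) < 1L)
    stop("a volume needs equally many slices and masks (>= 1)")
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]), dim(masks[[i]])))
      stop("slice ", i, " and its mask have different shapes")
  }
  structure(list(patient_id = as.character(patient_id), slices = slices,
                 masks = masks, modality_tag = modality_tag),
            class = "volume_record")
}

#' @export
print.volume_record <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<volume_record> patient=%s slices=%d size=%dx%d tag=%s\n",
              x$patient_id, length(x$slices), d[1], d[2], x$modality_tag))
  invisible(x)
}

#' Read an image/mask slice stack
#'
#' Two layouts are supported.  `nifti_volume`: `path` and `mask_path` name
#' paired NIfTI volumes; axial slices are taken along the last axis.
#' `image_directory`: `path` is a directory of 2-d PNG/TIFF slice files in
#' which every image `stem.ext` pairs with a mask `stem<mask_suffix>.ext`;
#' files are ordered by name.  PNG/TIFF intensities (read in `[0, 1]`) are
#' rescaled to the nominal `[0, 255]` range.
#'
#' @param path NIfTI file or slice directory.
#' @param layout `"nifti_volume"` or `"image_directory"`.
#' @param mask_path Mask volume path (required for `nifti_volume`).
#' @param mask_suffix Filename-stem suffix identifying mask files.
#' @param patient_id Identifier; defaults to the file/directory stem.
#' @param modality_tag Free-text tag stored on the record.
#' @return A `volume_record` with aligned `slices` and `masks` lists.
#' @export
read_slice_stack <- function(path, layout = c("nifti_volume", "image_directory"),
                             mask_path = NULL, mask_suffix = "_mask",
                             patient_id = NULL, modality_tag = "") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (layout == "nifti_volume") {
    if (is.null(mask_path)) stop("nifti_volume layout requires mask_path")
    if (!file.exists(mask_path)) stop("mask volume missing: ", mask_path)
    img <- as.array(RNifti::readNifti(path))
    msk <- as.array(RNifti::readNifti(mask_path))
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    if (length(dim(msk)) == 2L) dim(msk) <- c(dim(msk), 1L)
    if (!identical(dim(img), dim(msk)))
      stop("image volume ", paste(dim(img), collapse = "x"),
           " does not align with mask volume ", paste(dim(msk), collapse = "x"))
    ns <- dim(img)[3]
    if (is.null(patient_id))
      patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
    new_volume_record(patient_id,
                      lapply(seq_len(ns), function(k) img[, , k]),
                      lapply(seq_len(ns), function(k) msk[, , k]),
                      modality_tag)
  } else {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no PNG/TIFF files in ", path)
    stems <- tools::file_path_sans_ext(files)
    is_mask <- endsWith(stems, mask_suffix)
    imgs <- files[!is_mask]
    masks <- files[is_mask]
    mask_stems <- sub(paste0(mask_suffix, "$"), "",
                      tools::file_path_sans_ext(masks))
    img_stems <- tools::file_path_sans_ext(imgs)
    orphan_img <- setdiff(img_stems, mask_stems)
    orphan_msk <- setdiff(mask_stems, img_stems)
    if (length(orphan_img) || length(orphan_msk))
      stop("unpaired files in ", path, ": ",
           paste(c(orphan_img, paste0(orphan_msk, mask_suffix)), collapse = ", "))
    ord <- order(img_stems)
    read_gray <- function(f) {
      fp <- file.path(path, f)
      a <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(fp)
           else read_tiff_gray(fp)
      if (length(dim(a)) == 3L) a <- a[, , 1]
      a * 255
    }
    slices <- lapply(imgs[ord], read_gray)
    mask_of <- function(stem) masks[match(stem, mask_stems)]
    msks <- lapply(img_stems[ord], function(s) {
      m <- read_gray(mask_of(s))
      (m > 127) * 1
    })
    if (is.null(patient_id)) patient_id <- basename(normalizePath(path))
    new_volume_record(patient_id, slices, msks, modality_tag)
  }
}

read_tiff_gray <- function(fp) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF slices requires the 'tiff' package")
  tiff::readTIFF(fp)
}

#' Preprocess a grayscale slice into a network input tensor
#'
#' Resizes with bilinear interpolation to `size` x `size`, maps the nominal
#' `[0, 255]` intensity range affinely to `[-1, 1]` via `v / 127.5 - 1`
#' (clipping to the range), and replicates the channel three times.
#' Inputs whose values fall outside `[0, 255]` (raw MRI dynamic ranges)
#' are first min-max rescaled to `[0, 255]`.
#'
#' @param slice 2-d numeric matrix of finite intensities.
#' @param size Output side length (default 256).
#' @return `(size, size, 3)` array in `[-1, 1]` with identical channels.
#' @export
preprocess_image <- function(slice, size = 256L) {
  if (!is.matrix(slice)) stop("slice must be a 2-d matrix")
  if (!all(is.finite(slice))) stop("slice contains non-finite values")
  rng <- range(slice)
  if (rng[1] < 0 || rng[2] > 255) {
    slice <- if (rng[2] > rng[1]) (slice - rng[1]) / (rng[2] - rng[1]) * 255
             else slice * 0
  }
  x <- slice
  dim(x) <- c(dim(slice), 1L, 1L)
  x <- cpp_resize_bilinear_fwd(x, as.integer(size), as.integer(size))
  x <- pmin(pmax(x / 127.5 - 1, -1), 1)
  out <- array(0, c(size, size, 3L))
  out[, , 1] <- x
  out[, , 2] <- x
  out[, , 3] <- x
  out
}

#' Preprocess a label mask into a binary target
#'
#' Nearest-neighbour resizes to `size` x `size` and maps every strictly
#' positive label to 1, everything else to 0.
#'
#' @param mask 2-d numeric matrix of labels.
#' @param size Output side length (default 256).
#' @return `(size, size)` matrix of 0/1.
#' @export
preprocess_mask <- function(mask, size = 256L) {
  if (!is.matrix(mask)) stop("mask must be a 2-d matrix")
  size <- as.integer(size)
  d <- dim(mask)
  ri <- pmin(pmax(floor((seq_len(size) - 0.5) * d[1] / size) + 1L, 1L), d[1])
  ci <- pmin(pmax(floor((seq_len(size) - 0.5) * d[2] / size) + 1L, 1L), d[2])
  (mask[ri, ci, drop = FALSE] > 0) * 1
}

#' Build one preprocessed training/evaluation sample
#'
#' @param volume A `volume_record`.
#' @param slice_index 1-based slice index within the volume.
#' @param size Network input side length.
#' @return A `slice_sample`: preprocessed `image`, binary `mask`,
#'   `patient_id`, `slice_index` and a `preprocessed` provenance flag that
#'   guards against double application of the intensity map.
#' @export
make_slice_sample <- function(volume, slice_index, size = 256L) {
  stopifnot(inherits(volume, "volume_record"))
  structure(list(image = preprocess_image(volume$slices[[slice_index]], size),
                 mask = preprocess_mask(volume$masks[[slice_index]], size),
                 patient_id = volume$patient_id,
                 slice_index = as.integer(slice_index),
                 preprocessed = TRUE),
            class = "slice_sample")
}

#' Patient-level 70/10/20 split
#'
#' Shuffles the patient ids with the given seed, then assigns
#' `floor(0.7 N)` to training, `floor(0.2 N + 0.5)` (round half up) to
#' testing and the remainder to validation, reading the shuffled order as
#' train block, validation block, test block.  For 95 patients this gives
#' 66/10/19 and for 318 patients 222/32/64.
#'
#' @param patient_ids Unique, non-empty character vector.
#' @param seed Integer shuffle seed.
#' @return A list of class `patient_split` with `train_ids`, `val_ids`,
#'   `test_ids`, `ratios` and `seed`.
#' @export
split_patients <- function(patient_ids, seed = 42L) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (n < 3L) stop("need at least 3 patients to populate three subsets")
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique")
  shuffled <- withr_seed(seed, sample(patient_ids))
  n_train <- floor(0.7 * n)
  n_test <- floor(0.2 * n + 0.5)
  n_val <- n - n_train - n_test
  structure(list(train_ids = shuffled[seq_len(n_train)],
                 val_ids = shuffled[n_train + seq_len(n_val)],
                 test_ids = shuffled[n_train + n_val + seq_len(n_test)],
                 ratios = c(train = 0.7, val = 0.1, test = 0.2),
                 seed = as.integer(seed)),
            class = "patient_split")
}

#' @export
print.patient_split <- function(x, ...) {
  cat(sprintf("<patient_split> train=%d val=%d test=%d (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Write / read a split manifest CSV
#'
#' @param split A `patient_split`.
#' @param path CSV path; columns `patient_id`, `subset`.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "patient_split"))
  df <- data.frame(
    patient_id = c(split$train_ids, split$val_ids, split$test_ids),
    subset = rep(c("train", "val", "test"),
                 c(length(split$train_ids), length(split$val_ids),
                   length(split$test_ids))),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @return `read_split_manifest()` returns the manifest data frame.
#' @export
read_split_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Uniform per-patient slice sampling
#'
#' Deterministically selects up to `max_slices` slices from a volume.  With
#' `S` slices and `S <= max_slices` all indices are returned; otherwise the
#' unique rounded values of `max_slices` evenly spaced positions over the
#' slice range, so the first and last slices are always included.  The
#' selection involves no randomness and is therefore identical across runs.
#'
#' @param volume A `volume_record` (or an integer slice count).
#' @param max_slices Cap on the number of selected slices.
#' @return Strictly ascending 1-based integer slice indices.
#' @export
sample_slices <- function(volume, max_slices = 50L) {
  s <- if (inherits(volume, "volume_record")) length(volume$slices)
       else as.integer(volume)
  if (is.na(s) || s < 1L) stop("volume has no slices")
  max_slices <- as.integer(max_slices)
  if (max_slices < 1L) stop("max_slices must be >= 1")
  if (s <= max_slices) return(seq_len(s))
  unique(as.integer(round(seq(1L, s, length.out = max_slices))))
}
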