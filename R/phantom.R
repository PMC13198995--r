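# Seeded generator of liver-like 2-d phantom volumes.
#
# Each patient is a stack of axial slices containing one smooth,
# star-shaped foreground region: an ellipse whose radius is modulated by
# low-frequency harmonics, with centre, axes and modulation phase drifting
# smoothly from slice to slice so that neighbouring slices are correlated
# (as in real per-patient volumes, which makes slice- and patient-level
# aggregation differ measurably).  Images are foreground/background mean
# intensities shaped by a multiplicative low-frequency bias field plus
# Gaussian noise, clipped to [0, 255].  A configurable fraction of slices
# at both ends of the stack carries an empty mask, mimicking
# background-only slices above and below the liver.  Everything is fully
# determined by (seed, patient_index).

#' Phantom dataset specification
#'
#' Two intensity profiles are provided: `"t1"` (bright liver on a dark
#' background, moderate noise) and `"t2"` (darker liver on a brighter
#' background with higher noise), mirroring the qualitative contrast
#' difference between T1- and T2-weighted abdominal MRI.  These are test
#' presets, not physical simulations.
#'
#' @param n_patients Number of patient volumes.
#' @param slices_per_patient Slices per volume.
#' @param image_size Square slice side, >= 64.
#' @param fg_area_range Allowed foreground area fraction per liver slice.
#' @param contrast Foreground minus background mean intensity (0-255
#'   units); profile default when `NULL`.
#' @param noise_sd Additive Gaussian noise standard deviation; profile
#'   default when `NULL`.
#' @param bias_strength Amplitude of the multiplicative low-frequency bias
#'   field.
#' @param background_slice_fraction Fraction of slices (taken from both
#'   stack ends) with empty masks.
#' @param profile `"t1"` or `"t2"`.
#' @param seed Master seed; volumes depend only on `(seed, patient_index)`.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 20L, slices_per_patient = 10L,
                         image_size = 128L, fg_area_range = c(0.05, 0.35),
                         contrast = NULL, noise_sd = NULL,
                         bias_strength = 0.15,
                         background_slice_fraction = 0.2,
                         profile = c("t1", "t2"), seed = 42L) {
  profile <- match.arg(profile)
  if (is.null(contrast)) contrast <- if (profile == "t1") 90 else -70
  if (is.null(noise_sd)) noise_sd <- if (profile == "t1") 8 else 12
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop("image_size must be >= 64")
  if (any(fg_area_range < 0) || any(fg_area_range > 1) ||
      diff(fg_area_range) <= 0)
    stop("fg_area_range must be an increasing fraction interval in [0, 1]")
  if (fg_area_range[1] > 0.5)
    stop("fg_area_range infeasible: a star-shaped region of that size ",
         "cannot fit the image")
  if (background_slice_fraction < 0 || background_slice_fraction > 1)
    stop("background_slice_fraction must be in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 slices_per_patient = as.integer(slices_per_patient),
                 image_size = image_size, fg_area_range = fg_area_range,
                 contrast = contrast, noise_sd = noise_sd,
                 bias_strength = bias_strength,
                 background_slice_fraction = background_slice_fraction,
                 profile = profile, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Star-shaped liver-like mask: ellipse with harmonic boundary modulation.
phantom_mask <- function(size, cx, cy, a, b, amps, phases, fg_range) {
  xs <- matrix(seq_len(size), size, size)
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  target <- NULL
  for (iter in 1:6) {
    dx <- (xs - cx) / a
    dy <- (ys - cy) / b
    rho <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    mod <- 1
    for (k in seq_along(amps)) mod <- mod + amps[k] * cos((k + 1) * theta + phases[k])
    mask <- (rho <= mod) * 1
    frac <- mean(mask)
    if (frac >= fg_range[1] && frac <= fg_range[2]) return(mask)
    if (is.null(target)) target <- mean(fg_range)
    scale <- sqrt(target / max(frac, 1e-6))
    a <- a * scale
    b <- b * scale
  }
  mask
}

#' Generate one phantom patient volume
#'
#' @param spec A [phantom_spec()].
#' @param patient_index Positive integer; with `spec$seed` it fully
#'   determines the volume.
#' @return A `volume_record` with `modality_tag = spec$profile`.
#' @export
make_phantom_volume <- function(spec, patient_index) {
  stopifnot(inherits(spec, "phantom_spec"), patient_index >= 1)
  size <- spec$image_size
  s <- spec$slices_per_patient
  withr_seed((spec$seed * 100003L + as.integer(patient_index) * 7919L) %%
               .Machine$integer.max, {
    n_bg <- min(round(spec$background_slice_fraction * s), s - 1L)
    n_lo <- n_bg %/% 2L
    n_hi <- n_bg - n_lo
    liver_idx <- seq.int(n_lo + 1L, s - n_hi)
    # patient-level anatomy with smooth per-slice drift
    f_mid <- stats::runif(1, spec$fg_area_range[1] + 0.2 * diff(spec$fg_area_range),
                          spec$fg_area_range[2] - 0.2 * diff(spec$fg_area_range))
    q <- stats::runif(1, 0.6, 0.9)
    cx0 <- stats::runif(1, 0.4, 0.6) * size
    cy0 <- stats::runif(1, 0.4, 0.6) * size
    amps <- stats::runif(3, 0, 0.07)
    phases <- stats::runif(3, 0, 2 * pi)
    drift_phase <- stats::runif(4, 0, 2 * pi)
    drift_amp <- c(stats::runif(2, 0, 0.04) * size, stats::runif(2, 0, 0.15))
    bias_phase <- stats::runif(2, 0, pi)
    bg_mean <- if (spec$profile == "t1") 60 else 140
    slices <- vector("list", s)
    masks <- vector("list", s)
    xs <- matrix(seq_len(size) / size, size, size)
    ys <- matrix(seq_len(size) / size, size, size, byrow = TRUE)
    bias <- 1 + spec$bias_strength *
      cos(pi * xs + bias_phase[1]) * cos(pi * ys + bias_phase[2])
    for (k in seq_len(s)) {
      if (k %in% liver_idx) {
        t <- (k - liver_idx[1]) / max(length(liver_idx) - 1L, 1L)
        cx <- cx0 + drift_amp[1] * sin(2 * pi * t + drift_phase[1])
        cy <- cy0 + drift_amp[2] * sin(2 * pi * t + drift_phase[2])
        f_t <- f_mid * (1 + drift_amp[3] * sin(2 * pi * t + drift_phase[3]))
        a <- sqrt(f_t * size^2 / (pi * q))
        b <- a * q
        ph <- phases + drift_amp[4] * sin(2 * pi * t + drift_phase[4])
        masks[[k]] <- phantom_mask(size, cx, cy, a, b, amps, ph,
                                   spec$fg_area_range)
      } else {
        masks[[k]] <- matrix(0, size, size)
      }
      img <- (bg_mean + spec$contrast * masks[[k]]) * bias +
        matrix(stats::rnorm(size^2, sd = spec$noise_sd), size, size)
      slices[[k]] <- pmin(pmax(img, 0), 255)
    }
  })
  new_volume_record(sprintf("P%03d", as.integer(patient_index)), slices, masks,
                    modality_tag = spec$profile)
}

#' Generate and write a phantom dataset
#'
#' @param spec A [phantom_spec()].
#' @param dir Output directory (created if needed); `NULL` keeps the
#'   volumes in memory only.
#' @param format `"nifti"` (uncompressed `.nii` image/mask volume pairs)
#'   or `"png"` (per-patient slice directories with `_mask` files).
#' @return A list: `volumes` (list of `volume_record`) and `manifest`
#'   (data frame `patient_id`, `n_slices`, `profile`, `seed`, plus file
#'   paths when written).  The manifest is also written as
#'   `manifest.csv` under `dir`.
#' @export
make_phantom_dataset <- function(spec, dir = NULL, format = c("nifti", "png")) {
  format <- match.arg(format)
  volumes <- lapply(seq_len(spec$n_patients), function(i)
    make_phantom_volume(spec, i))
  manifest <- data.frame(
    patient_id = vapply(volumes, function(v) v$patient_id, character(1)),
    n_slices = vapply(volumes, function(v) length(v$slices), integer(1)),
    profile = spec$profile, seed = spec$seed, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    img_files <- character(spec$n_patients)
    mask_files <- character(spec$n_patients)
    for (i in seq_along(volumes)) {
      v <- volumes[[i]]
      size <- dim(v$slices[[1]])
      if (format == "nifti") {
        arr_i <- array(unlist(v$slices), c(size, length(v$slices)))
        arr_m <- array(unlist(v$masks), c(size, length(v$masks)))
        img_files[i] <- file.path(dir, paste0(v$patient_id, "_img.nii"))
        mask_files[i] <- file.path(dir, paste0(v$patient_id, "_mask.nii"))
        RNifti::writeNifti(RNifti::asNifti(arr_i), img_files[i])
        RNifti::writeNifti(RNifti::asNifti(arr_m), mask_files[i])
      } else {
        pdir <- file.path(dir, v$patient_id)
        if (!dir.exists(pdir)) dir.create(pdir)
        for (k in seq_along(v$slices)) {
          png::writePNG(v$slices[[k]] / 255,
                        file.path(pdir, sprintf("slice%03d.png", k)))
          png::writePNG(v$masks[[k]],
                        file.path(pdir, sprintf("slice%03d_mask.png", k)))
        }
        img_files[i] <- pdir
        mask_files[i] <- pdir
      }
    }
    manifest$image_path <- img_files
    manifest$mask_path <- mask_files
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(volumes = volumes, manifest = manifest)
}

#' Preprocess selected slices of phantom volumes into training samples
#'
#' Convenience bridging the generator and the training harness: for every
#' requested patient the uniform slice sampler picks up to `max_slices`
#' slices, each preprocessed to the network input size.
#'
#' @param volumes List of `volume_record`s.
#' @param ids Patient ids to include (default: all).
#' @param size Network input size.
#' @param max_slices Per-patient slice cap (see [sample_slices()]).
#' @return List of `slice_sample`s.
#' @export
phantom_samples <- function(volumes, ids = NULL, size = 256L, max_slices = 50L) {
  if (!is.null(ids))
    volumes <- Filter(function(v) v$patient_id %in% ids, volumes)
  out <- list()
  for (v in volumes) {
    for (k in sample_slices(v, max_slices)) {
      out[[length(out) + 1L]] <- make_slice_sample(v, k, size)
    }
  }
  out
}
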