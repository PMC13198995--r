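# Overlap and surface-distance evaluation metrics: IoU, Dice, HD95, ASSD,
# with slice- and patient-level aggregation.

check_binary <- function(m, what) {
  if (!all(m %in% c(0, 1))) stop(what, " must be binary (0/1)")
  invisible(NULL)
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred_bin,gt Binary matrices of identical shape.
#' @return A list `TP`, `FP`, `FN`, `TN` (pixel counts).
#' @export
confusion_counts <- function(pred_bin, gt) {
  if (!identical(dim(pred_bin), dim(gt))) stop("mask shapes differ")
  check_binary(pred_bin, "pred_bin"); check_binary(gt, "gt")
  tp <- sum(pred_bin == 1 & gt == 1)
  fp <- sum(pred_bin == 1 & gt == 0)
  fn <- sum(pred_bin == 0 & gt == 1)
  list(TP = tp, FP = fp, FN = fn, TN = length(gt) - tp - fp - fn)
}

#' Overlap metrics: IoU and Dice
#'
#' `IoU = TP / (TP + FP + FN)` and `Dice = 2 TP / (2 TP + FP + FN)`.
#' When both masks are empty the overlap is perfect by convention and both
#' metrics are 1.
#'
#' @inheritParams confusion_counts
#' @return A list with `iou` and `dice` in `[0, 1]`.
#' @export
overlap_metrics <- function(pred_bin, gt) {
  cc <- confusion_counts(pred_bin, gt)
  denom_iou <- cc$TP + cc$FP + cc$FN
  if (denom_iou == 0) return(list(iou = 1, dice = 1))
  list(iou = cc$TP / denom_iou,
       dice = 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
}

#' Boundary pixels of a binary mask
#'
#' A boundary pixel is a foreground pixel with at least one background
#' 4-neighbour; pixels on the image border count the outside as background.
#'
#' @param mask Binary matrix.
#' @return Integer matrix of (row, col) coordinates, possibly 0-row.
#' @export
boundary_points <- function(mask) {
  check_binary(mask, "mask")
  d <- dim(mask)
  pad <- matrix(0, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
  nb_min <- pmin(pad[1:d[1], 2:(d[2] + 1L)], pad[3:(d[1] + 2L), 2:(d[2] + 1L)],
                 pad[2:(d[1] + 1L), 1:d[2]], pad[2:(d[1] + 1L), 3:(d[2] + 2L)])
  which(core == 1 & nb_min == 0, arr.ind = TRUE)
}

# Distance from every pixel to the nearest point of `pts` via an exact
# Euclidean distance map (pixels at `pts` are 0).
dist_to_points <- function(pts, d) {
  img <- matrix(1, d[1], d[2])
  img[pts] <- 0
  EBImage::distmap(img, metric = "euclidean")
}

#' Surface distances: HD95 and ASSD
#'
#' Boundaries are extracted as in [boundary_points()]; `d(x, S)` is the
#' minimum Euclidean distance in pixel units.  HD95 is the maximum of the
#' two directed 95th percentiles (linear-interpolation percentile), and
#' ASSD is the symmetric mean of all directed boundary distances:
#' `(sum_x d(x, S_B) + sum_y d(y, S_A)) / (|S_A| + |S_B|)`.
#' If either mask is empty the result is flagged invalid rather than
#' raising an error, matching the slice-validity convention used in
#' aggregation.
#'
#' @param a,b Binary masks of identical shape.
#' @return A list `hd95`, `assd` (pixels; `NA` when invalid) and `valid`.
#' @export
surface_distances <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  check_binary(a, "a"); check_binary(b, "b")
  pa <- boundary_points(a)
  pb <- boundary_points(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    return(list(hd95 = NA_real_, assd = NA_real_, valid = FALSE))
  d <- dim(a)
  da <- dist_to_points(pb, d)[pa]   # d(x, S_B) for x in S_A
  db <- dist_to_points(pa, d)[pb]   # d(y, S_A) for y in S_B
  hd95 <- max(stats::quantile(da, 0.95, type = 7, names = FALSE),
              stats::quantile(db, 0.95, type = 7, names = FALSE))
  assd <- (sum(da) + sum(db)) / (length(da) + length(db))
  list(hd95 = hd95, assd = assd, valid = TRUE)
}

#' Per-slice metrics record
#'
#' Computes all four metrics for one predicted/reference mask pair.
#'
#' @param pred_bin,gt Binary masks.
#' @param patient_id,slice_index Identity attached to the record.
#' @return One-row data frame: `patient_id`, `slice_index`, `iou`, `dice`,
#'   `hd95`, `assd`, `valid_distance`.
#' @export
slice_metrics <- function(pred_bin, gt, patient_id = "", slice_index = NA_integer_) {
  ov <- overlap_metrics(pred_bin, gt)
  sd <- surface_distances(pred_bin, gt)
  data.frame(patient_id = patient_id, slice_index = slice_index,
             iou = ov$iou, dice = ov$dice, hd95 = sd$hd95, assd = sd$assd,
             valid_distance = sd$valid, stringsAsFactors = FALSE)
}

#' Aggregate slice metrics
#'
#' Slice level: mean and standard deviation over all records (distance
#' metrics over valid records only).  Patient level: per-patient means
#' first (distances over that patient's valid slices), then mean and
#' standard deviation over patients.  A distance metric with no valid
#' record is reported as `NA` with `n = 0`.
#'
#' @param records Data frame as produced by [slice_metrics()].
#' @param level `"slice"` or `"patient"`.
#' @return Data frame: `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(records, level = c("slice", "patient")) {
  level <- match.arg(level)
  if (nrow(records) == 0L) stop("no records to aggregate")
  metrics <- c("iou", "dice", "hd95", "assd")
  if (level == "patient") {
    per_pat <- lapply(split(records, records$patient_id), function(r) {
      vals <- vapply(metrics, function(m) {
        v <- r[[m]]
        if (m %in% c("hd95", "assd")) v <- v[r$valid_distance]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, numeric(1))
      as.data.frame(as.list(vals))
    })
    records <- do.call(rbind, per_pat)
    records$valid_distance <- !is.na(records$hd95)
  }
  do.call(rbind, lapply(metrics, function(m) {
    v <- records[[m]]
    if (m %in% c("hd95", "assd")) v <- v[records$valid_distance & !is.na(v)]
    data.frame(metric = m,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
}

#' Write per-slice metrics and summaries as CSV
#'
#' @param records Per-slice metrics data frame.
#' @param path Output CSV; summary rows (per requested level) are appended
#'   with `patient_id = "__summary_<level>__"`.
#' @param levels Aggregation levels to append.
#' @export
write_metrics_csv <- function(records, path, levels = c("slice", "patient")) {
  out <- records
  for (lv in levels) {
    s <- aggregate_metrics(records, lv)
    srow <- data.frame(patient_id = paste0("__summary_", lv, "__"),
                       slice_index = NA_integer_,
                       iou = s$mean[s$metric == "iou"],
                       dice = s$mean[s$metric == "dice"],
                       hd95 = s$mean[s$metric == "hd95"],
                       assd = s$mean[s$metric == "assd"],
                       valid_distance = NA, stringsAsFactors = FALSE)
    out <- rbind(out, srow)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
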