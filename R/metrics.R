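#' Voxel-wise confusion counts between two masks
#'
#' @param pred,gt [mask_volume()] objects on the same grid.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`, `n`.
#' @examples
#' a <- mask_volume(matrix(c(1, 1, 0, 0), 2))
#' b <- mask_volume(matrix(c(1, 0, 1, 0), 2))
#' confusion_counts(a, b)
#' @export
confusion_counts <- function(pred, gt) {
  check_same_grid(pred, gt)
  p <- pred$voxels == 1L
  g <- gt$voxels == 1L
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  tn <- sum(!p & !g)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("%s undefined (zero denominator); returning NaN", what))
    return(NaN)
  }
  num / den
}

metrics_from_counts <- function(tp, fp, fn, tn) {
  # double precision up front: count products overflow 32-bit integers
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  n <- tp + fp + fn + tn
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  tibble(
    accuracy = safe_ratio(tp + tn, n, "accuracy"),
    sensitivity = safe_ratio(tp, tp + fn, "sensitivity"),
    precision = safe_ratio(tp, tp + fp, "precision"),
    specificity = safe_ratio(tn, tn + fp, "specificity"),
    dsc = safe_ratio(2 * tp, 2 * tp + fp + fn, "dsc"),
    iou = safe_ratio(tp, tp + fp + fn, "iou"),
    mcc = safe_ratio(tp * tn - fp * fn, mcc_den, "mcc")
  )
}

#' Segmentation evaluation metric suite
#'
#' Computes the eight standard overlap and boundary metrics between a predicted
#' and a ground-truth binary mask: accuracy, sensitivity (recall), precision,
#' specificity, Dice similarity coefficient (DSC), intersection-over-union
#' (IoU), Matthews correlation coefficient (MCC), and the symmetric
#' 95th-percentile Hausdorff distance in millimetres.
#'
#' Metrics are voxel-pooled over the whole volume by default (one value per
#' volume pair); [seg_metrics_by_slice()] gives per-slice rows for per-image
#' averaging.
#'
#' @param pred,gt [mask_volume()] objects on the same grid; `gt` should have at
#'   least one foreground voxel for the overlap metrics to be defined. Ratios
#'   with a zero denominator are reported as `NaN` with a warning.
#' @param hd95 compute the 95% Hausdorff distance (requires both masks
#'   nonempty); set `FALSE` to skip the boundary metric.
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `precision`, `specificity`, `dsc`, `iou`, `mcc`, `hd95`.
#' @examples
#' gt <- array(0L, c(1, 8, 8)); gt[1, 3:6, 3:6] <- 1L
#' pr <- gt; pr[1, 3, 3] <- 0L
#' seg_metrics(mask_volume(pr), mask_volume(gt))
#' @export
seg_metrics <- function(pred, gt, hd95 = TRUE) {
  cc <- confusion_counts(pred, gt)
  out <- metrics_from_counts(cc$tp, cc$fp, cc$fn, cc$tn)
  out$hd95 <- if (isTRUE(hd95)) hausdorff95(pred, gt) else NA_real_
  out
}

#' @rdname seg_metrics
#' @details `seg_metrics_by_slice()` computes the same metrics per slice
#'   (Hausdorff restricted in-plane); slices where both masks are empty yield
#'   `NaN` overlap ratios. Average with e.g. `dplyr::summarise()`.
#' @export
seg_metrics_by_slice <- function(pred, gt, hd95 = TRUE) {
  check_same_grid(pred, gt)
  ns <- dim(pred$voxels)[1]
  purrr::map_dfr(seq_len(ns), function(k) {
    pk <- mask_volume(pred$voxels[k, , , drop = FALSE],
                      pred$pixel_size, pred$slice_spacing)
    gk <- mask_volume(gt$voxels[k, , , drop = FALSE],
                      gt$pixel_size, gt$slice_spacing)
    cc <- confusion_counts(pk, gk)
    m <- suppressWarnings(metrics_from_counts(cc$tp, cc$fp, cc$fn, cc$tn))
    m$hd95 <- if (isTRUE(hd95) && sum(pk$voxels) > 0 && sum(gk$voxels) > 0) {
      hausdorff95(pk, gk)
    } else {
      NA_real_
    }
    dplyr::bind_cols(tibble(slice_index = k), m)
  })
}

boundary_voxel_coords <- function(mask) {
  v <- mask$voxels
  d <- dim(v)
  padded <- array(0L, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  sub3 <- function(i, j, k) padded[i, j, k, drop = FALSE]
  interior <- sub3(2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)) == 1L
  nb_bg <-
    (sub3(1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)) == 0L) |
    (sub3(3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)) == 0L) |
    (sub3(2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)) == 0L) |
    (sub3(2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)) == 0L) |
    (sub3(2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]) == 0L) |
    (sub3(2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)) == 0L)
  idx <- which(interior & nb_bg, arr.ind = TRUE)
  # voxel centers in physical mm; anisotropic spacing
  cbind(
    z = (idx[, 1] - 1) * mask$slice_spacing,
    y = (idx[, 2] - 1) * mask$pixel_size[2],
    x = (idx[, 3] - 1) * mask$pixel_size[1]
  )
}

directed_boundary_dists <- function(a, b) {
  # for each row of a: min Euclidean distance to rows of b (chunked)
  na <- nrow(a)
  out <- numeric(na)
  bb <- rowSums(b^2)
  chunk <- max(1L, floor(2e7 / nrow(b)))
  for (s in seq(1L, na, by = chunk)) {
    e <- min(na, s + chunk - 1L)
    aa <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), bb, "+") - 2 * tcrossprod(aa, b)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' 95th-percentile symmetric Hausdorff distance (mm)
#'
#' Boundary voxels are foreground voxels with at least one background
#' face-neighbour; distances are voxel-centre to voxel-centre in physical mm
#' under anisotropic spacing. Directed distances from both masks are pooled
#' and the percentile taken with linear interpolation.
#'
#' @inheritParams seg_metrics
#' @param percentile percentile of the pooled distance multiset (default 95;
#'   100 gives the classic max Hausdorff distance).
#' @return distance in mm.
#' @export
hausdorff95 <- function(pred, gt, percentile = 95) {
  check_same_grid(pred, gt)
  if (sum(pred$voxels) == 0L || sum(gt$voxels) == 0L) {
    abort("hausdorff95 requires both masks to be nonempty")
  }
  a <- boundary_voxel_coords(pred)
  b <- boundary_voxel_coords(gt)
  d <- c(directed_boundary_dists(a, b), directed_boundary_dists(b, a))
  if (percentile >= 100) return(max(d))
  unname(quantile(d, percentile / 100, type = 7))
}
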