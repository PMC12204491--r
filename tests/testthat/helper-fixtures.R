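# shared fixtures, all generated in code

# closed polygonal circle, vertex 1 exactly at angle 0
circle_contour <- function(r = 10, n = 256, cx = 0, cy = 0) {
  th <- 2 * pi * (0:(n - 1)) / n
  tibble::tibble(
    slice_index = 1L, z = 0, contour_id = 1L,
    x = cx + r * cos(th), y = cy + r * sin(th)
  )
}

# binary disk slice on an n x n grid (pixel-center rasterization)
disk_slice <- function(n = 64, r = 20, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  m <- matrix(0L, n, n)
  d2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`)
  m[d2 <= r^2] <- 1L
  m
}

mask_from_slices <- function(..., pixel_size = c(1, 1), slice_spacing = 1) {
  sl <- list(...)
  vox <- array(0L, c(length(sl), dim(sl[[1]])))
  for (k in seq_along(sl)) vox[k, , ] <- sl[[k]]
  mask_volume(vox, pixel_size, slice_spacing)
}

# brute-force oracles -------------------------------------------------------

# exact max Hausdorff distance between foreground voxel-center sets
brute_hausdorff_max <- function(a, b) {
  coords <- function(m) {
    idx <- which(m$voxels == 1L, arr.ind = TRUE)
    cbind(
      (idx[, 1] - 1) * m$slice_spacing,
      (idx[, 2] - 1) * m$pixel_size[2],
      (idx[, 3] - 1) * m$pixel_size[1]
    )
  }
  pa <- coords(a); pb <- coords(b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d <- sqrt(pmax(d2, 0))
  max(apply(d, 1, min), apply(d, 2, min))
}

# brute-force per-voxel metric suite from direct enumeration
brute_metrics <- function(pred, gt) {
  p <- as.vector(pred$voxels); g <- as.vector(gt$voxels)
  tp <- sum(p == 1 & g == 1); fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1); tn <- sum(p == 0 & g == 0)
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / length(p),
    sensitivity = tp / (tp + fn),
    precision = tp / (tp + fp),
    specificity = tn / (tn + fp),
    dsc = 2 * tp / (2 * tp + fp + fn),
    iou = tp / (tp + fp + fn),
    mcc = (tp * tn - fp * fn) /
      sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  )
}

# lazy cache for expensive solves shared across test files
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

solved_cylinder <- function() {
  cached_fixture("cyl_field", {
    mesh <- make_cylinder_mesh(10, 100, 48, 24)
    list(mesh = mesh,
         field = solve_membrane_stress(membrane_problem(mesh)))
  })
}

small_phantom <- function() {
  cached_fixture("small_phantom", make_fusiform_phantom(fusiform_spec(seed = 7)))
}
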