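#' Binary mask volume with physical spacing
#'
#' The common container for segmentations throughout the package: a 3D binary
#' array indexed `[slice, row, col]` together with the physical in-plane pixel
#' size and the slice spacing, both in millimetres. All downstream geometry
#' (contours, meshes, Hausdorff distances) is computed in this physical frame.
#'
#' @param voxels 3D array (slice, row, col) of 0/1 (logical or numeric).
#'   A 2D matrix is promoted to a single-slice volume.
#' @param pixel_size length-2 numeric, mm per pixel in-plane `(dx, dy)`
#'   (column direction, row direction). A scalar is recycled.
#' @param slice_spacing slice spacing `dz` in mm.
#' @return An object of class `mask_volume`.
#' @examples
#' m <- mask_volume(array(0L, c(2, 8, 8)), pixel_size = 0.85, slice_spacing = 3)
#' dim(m$voxels)
#' @export
mask_volume <- function(voxels, pixel_size = c(1, 1), slice_spacing = 1) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array (slice, row, col) or a 2D matrix.")
  }
  if (dim(voxels)[1] < 1L) abort("mask volume needs at least one slice")
  v <- voxels
  storage.mode(v) <- "integer"
  bad <- !(v %in% c(0L, 1L))
  if (any(bad)) abort("mask voxels must be binary (0/1)")
  pixel_size <- rep_len(as.numeric(pixel_size), 2L)
  slice_spacing <- as.numeric(slice_spacing)
  if (any(pixel_size <= 0) || slice_spacing <= 0) {
    abort("pixel_size and slice_spacing must be positive (mm)")
  }
  structure(
    list(voxels = v, pixel_size = pixel_size, slice_spacing = slice_spacing),
    class = "mask_volume"
  )
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<mask_volume> %d slice(s) of %d x %d px; pixel %.3g x %.3g mm, spacing %.3g mm; %d foreground voxels\n",
    d[1], d[2], d[3], x$pixel_size[1], x$pixel_size[2], x$slice_spacing,
    sum(x$voxels)
  ))
  invisible(x)
}

#' @export
dim.mask_volume <- function(x) dim(x$voxels)

is_mask_volume <- function(x) inherits(x, "mask_volume")

check_same_grid <- function(pred, gt) {
  if (!is_mask_volume(pred) || !is_mask_volume(gt)) {
    abort("both masks must be `mask_volume` objects")
  }
  if (!identical(dim(pred$voxels), dim(gt$voxels))) {
    abort("mask shapes differ")
  }
  if (max(abs(pred$pixel_size - gt$pixel_size)) > 1e-9 ||
      abs(pred$slice_spacing - gt$slice_spacing) > 1e-9) {
    abort("mask spacings differ")
  }
  invisible(TRUE)
}

#' Read / write mask volumes as NIfTI
#'
#' Voxel data are stored NIfTI-style `[x, y, z]`; this package's slice-major
#' layout `[slice, row, col]` maps to `(z, y, x)`. Spacing metadata travel in
#' the NIfTI header (`pixdim`).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_mask_nifti()` returns a [mask_volume()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  pd <- RNifti::pixdim(img)
  vox <- aperm(a != 0, c(3L, 2L, 1L)) * 1L
  mask_volume(vox, pixel_size = pd[1:2], slice_spacing = pd[3])
}

#' @param mask a [mask_volume()].
#' @rdname read_mask_nifti
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(is_mask_volume(mask))
  a <- aperm(mask$voxels, c(3L, 2L, 1L))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(mask$pixel_size, mask$slice_spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write mask volumes as per-slice PNG stacks
#'
#' A directory of `slice_0001.png`, ... plus a `spacing.json` sidecar holding
#' `pixel_size` (mm) and `slice_spacing` (mm). Requires the `png` package.
#'
#' @param dir directory containing the stack.
#' @return `read_mask_slices()` returns a [mask_volume()].
#' @export
read_mask_slices <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the `png` package is required for PNG stack I/O")
  }
  sc <- jsonlite::read_json(file.path(dir, "spacing.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) abort("no PNG slices found")
  slices <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    a > 0.5
  })
  vox <- array(0L, c(length(slices), dim(slices[[1]])))
  for (k in seq_along(slices)) vox[k, , ] <- slices[[k]] * 1L
  mask_volume(vox, pixel_size = sc$pixel_size, slice_spacing = sc$slice_spacing)
}

#' @rdname read_mask_slices
#' @param mask a [mask_volume()].
#' @export
write_mask_slices <- function(mask, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the `png` package is required for PNG stack I/O")
  }
  stopifnot(is_mask_volume(mask))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(pixel_size = mask$pixel_size, slice_spacing = mask$slice_spacing),
    file.path(dir, "spacing.json"),
    auto_unbox = FALSE, digits = NA
  )
  for (k in seq_len(dim(mask$voxels)[1])) {
    png::writePNG(
      mask$voxels[k, , ] * 1.0,
      file.path(dir, sprintf("slice_%04d.png", k))
    )
  }
  invisible(dir)
}
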