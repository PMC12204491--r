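#' Contour tables
#'
#' Contours are plain tibbles with columns `slice_index` (1-based), `z` (mm),
#' `contour_id` (within slice), `x`, `y` (mm), points ordered counter-clockwise
#' with the closing edge implicit (first point not repeated). Pixel `(r, c)`
#' (0-based) has its centre at `x = (c + 0.5) * dx`, `y = (r + 0.5) * dy`, so
#' contours live in the same physical frame as meshes and metrics.
#'
#' @name contour-tables
NULL

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

orient_ccw <- function(df) {
  if (shoelace_area(df$x, df$y) < 0) df[rev(seq_len(nrow(df))), ] else df
}

#' Extract sub-pixel contours from a binary mask
#'
#' Traces the 0.5 iso-level of each slice (marching-squares style via
#' [grDevices::contourLines()] on a zero-padded grid), yielding one closed
#' counter-clockwise polyline per connected foreground component, in physical
#' millimetres. Components enclosing less than `min_area_px` pixels of area
#' are dropped.
#'
#' @param mask a [mask_volume()], or a 2D binary matrix (then `pixel_size`
#'   must be given and a single-slice table is returned).
#' @param min_area_px minimum enclosed area, in pixel units (`dx*dy`), below
#'   which a contour is discarded. Default 2.
#' @param largest_only keep only the largest-area contour on each slice
#'   (useful when metal-artifact streaks fragment a slice).
#' @param pixel_size,slice_spacing used only when `mask` is a bare matrix.
#' @return A contour tibble (see [contour-tables]); zero rows if no contour
#'   survives.
#' @examples
#' m <- matrix(0L, 16, 16); m[5:12, 4:11] <- 1L
#' ct <- mask_to_contours(m, pixel_size = c(1, 1))
#' nrow(ct) > 0
#' @export
mask_to_contours <- function(mask, min_area_px = 2, largest_only = FALSE,
                             pixel_size = c(1, 1), slice_spacing = 1) {
  if (!is_mask_volume(mask)) mask <- mask_volume(mask, pixel_size, slice_spacing)
  dx <- mask$pixel_size[1]; dy <- mask$pixel_size[2]
  ns <- dim(mask$voxels)[1]
  out <- purrr::map_dfr(seq_len(ns), function(k) {
    sl <- mask$voxels[k, , ]
    if (sum(sl) == 0L) return(tibble())
    cl <- slice_iso_contours(sl, dx, dy)
    if (length(cl) == 0L) return(tibble())
    areas <- vapply(cl, function(p) abs(shoelace_area(p$x, p$y)), 0)
    keep <- areas >= min_area_px * dx * dy
    if (!any(keep)) return(tibble())
    cl <- cl[keep]; areas <- areas[keep]
    if (isTRUE(largest_only)) {
      cl <- cl[which.max(areas)]
    }
    purrr::imap_dfr(cl, function(p, i) {
      df <- orient_ccw(tibble(x = p$x, y = p$y))
      tibble(
        slice_index = k, z = (k - 1) * mask$slice_spacing,
        contour_id = i, x = df$x, y = df$y
      )
    })
  })
  if (nrow(out) == 0L) {
    out <- tibble(
      slice_index = integer(), z = numeric(), contour_id = integer(),
      x = numeric(), y = numeric()
    )
  }
  out
}

# separable [1 2 1]/4 smoothing; zero-padded borders. Applied before the
# iso-contour so the 0.5 level sits sub-pixel on the true boundary instead of
# the marching-squares staircase (binary input overestimates perimeters).
smooth121 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  h <- (p[1:nr, 2:(nc + 1)] + 2 * p[2:(nr + 1), 2:(nc + 1)] +
          p[3:(nr + 2), 2:(nc + 1)]) / 4
  p[2:(nr + 1), 2:(nc + 1)] <- h
  (p[2:(nr + 1), 1:nc] + 2 * p[2:(nr + 1), 2:(nc + 1)] +
     p[2:(nr + 1), 3:(nc + 2)]) / 4
}

slice_iso_contours <- function(sl, dx, dy) {
  sl <- smooth121(sl)
  nr <- nrow(sl); nc <- ncol(sl)
  z <- matrix(0, nc + 2L, nr + 2L)
  z[2:(nc + 1), 2:(nr + 1)] <- t(sl) # contourLines wants z[x, y]
  xg <- ((0:(nc + 1)) - 0.5) * dx    # padded pixel centers
  yg <- ((0:(nr + 1)) - 0.5) * dy
  cl <- grDevices::contourLines(xg, yg, z, levels = 0.5)
  lapply(cl, function(p) {
    x <- p$x; y <- p$y
    n <- length(x)
    if (n > 1 && abs(x[1] - x[n]) < 1e-12 && abs(y[1] - y[n]) < 1e-12) {
      x <- x[-n]; y <- y[-n]
    }
    list(x = x, y = y)
  })
}

check_contour <- function(contour, min_points = 3L) {
  if (!is.data.frame(contour) || !all(c("x", "y") %in% names(contour))) {
    abort("a contour must be a data frame with columns `x` and `y`")
  }
  if (nrow(contour) < min_points) {
    abort(sprintf("contour must have at least %d points", min_points))
  }
  invisible(TRUE)
}

#' Rasterize a closed contour onto a pixel grid
#'
#' Even-odd polygon fill: a pixel is foreground when its centre lies inside
#' the polygon (centre convention as in [mask_to_contours()]).
#'
#' @param contour data frame with columns `x`, `y` (mm), one closed polygon.
#' @param dim `c(nrow, ncol)` of the target grid.
#' @param pixel_size mm per pixel `(dx, dy)`.
#' @return binary integer matrix `dim[1] x dim[2]`.
#' @export
contour_to_mask <- function(contour, dim, pixel_size = c(1, 1)) {
  check_contour(contour)
  pixel_size <- rep_len(as.numeric(pixel_size), 2L)
  dx <- pixel_size[1]; dy <- pixel_size[2]
  xmax <- dim[2] * dx; ymax <- dim[1] * dy
  if (any(contour$x < 0) || any(contour$y < 0) ||
      any(contour$x > xmax) || any(contour$y > ymax)) {
    abort("contour extends outside the target grid")
  }
  centers <- expand.grid(
    r = seq_len(dim[1]) - 1L, c = seq_len(dim[2]) - 1L
  )
  px <- (centers$c + 0.5) * dx
  py <- (centers$r + 0.5) * dy
  bnd <- rbind(
    cbind(contour$x, contour$y),
    c(contour$x[1], contour$y[1])
  )
  inside <- mgcv::in.out(bnd, cbind(px, py))
  m <- matrix(0L, dim[1], dim[2])
  m[cbind(centers$r + 1L, centers$c + 1L)] <- as.integer(inside)
  m
}

#' Rasterize a full contour table back into a mask volume
#'
#' Inverse of [mask_to_contours()] at the volume level; slices without
#' contours come back empty. Multiple contours on a slice are OR-combined.
#'
#' @param contours contour tibble (see [contour-tables]).
#' @param dim `c(n_slices, nrow, ncol)`.
#' @inheritParams contour_to_mask
#' @param slice_spacing mm between slices.
#' @return a [mask_volume()].
#' @export
contours_to_mask <- function(contours, dim, pixel_size = c(1, 1),
                             slice_spacing = 1) {
  vox <- array(0L, dim)
  if (nrow(contours) > 0) {
    split_keys <- interaction(contours$slice_index, contours$contour_id,
                              drop = TRUE)
    for (piece in split(contours, split_keys)) {
      k <- piece$slice_index[1]
      m <- contour_to_mask(piece, dim[2:3], pixel_size)
      vox[k, , ] <- pmax(vox[k, , ], m)
    }
  }
  mask_volume(vox, pixel_size, slice_spacing)
}

#' Resample a closed contour to n equally spaced points
#'
#' Points are spaced equally by arc length along the closed polyline. The
#' start point is fixed by convention at the vertex whose direction from the
#' contour centroid points most strongly along +x, so that independently
#' resampled contours share a common angular origin (needed for lofting).
#'
#' @param contour data frame with `x`, `y` columns (single closed polygon);
#'   extra columns (`slice_index`, `z`, ...) are carried over from the first
#'   row.
#' @param n number of output points (>= 3).
#' @return tibble with the same columns, `n` rows.
#' @export
resample_contour <- function(contour, n) {
  check_contour(contour)
  if (n < 3) abort("need n >= 3 points")
  x <- contour$x; y <- contour$y
  cx <- mean(x); cy <- mean(y)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  dirx <- ifelse(r > 0, (x - cx) / r, -Inf)
  start <- which.max(dirx)
  ord <- c(start:length(x), seq_len(start - 1L))
  x <- x[ord]; y <- y[ord]
  # closed polyline: append the start to close the loop
  xc <- c(x, x[1]); yc <- c(y, y[1])
  seg <- sqrt(diff(xc)^2 + diff(yc)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) abort("degenerate contour (zero perimeter)")
  si <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  xi <- approx(s, xc, xout = si, ties = "ordered")$y
  yi <- approx(s, yc, xout = si, ties = "ordered")$y
  out <- contour[rep(1L, n), , drop = FALSE]
  out$x <- xi; out$y <- yi
  tibble::remove_rownames(as_tibble(out))
}

#' Hydraulic diameter of a cross-sectional contour
#'
#' `D_h = 4 A / P` with shoelace area `A` and polygonal perimeter `P`; equal
#' to the geometric diameter for a circle and to the side length for a square.
#'
#' @param contour data frame with `x`, `y` (mm), a single closed polygon.
#' @return diameter in mm.
#' @export
hydraulic_diameter <- function(contour) {
  check_contour(contour)
  a <- abs(shoelace_area(contour$x, contour$y))
  p <- polygon_perimeter(contour$x, contour$y)
  if (a <= 0 || p <= 0) abort("degenerate contour")
  4 * a / p
}

#' Per-slice hydraulic diameter profile
#'
#' @param contours contour tibble; on slices with several contours the
#'   largest-area one is used.
#' @return tibble with columns `slice_index`, `z`, `d_h` (mm).
#' @export
diameter_profile <- function(contours) {
  if (nrow(contours) == 0L) abort("no contours supplied")
  contours |>
    dplyr::group_by(.data$slice_index, .data$contour_id) |>
    dplyr::summarise(
      z = .data$z[1],
      area = abs(shoelace_area(.data$x, .data$y)),
      d_h = hydraulic_diameter(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$slice_index) |>
    dplyr::slice_max(.data$area, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("slice_index", "z", "d_h")
}

#' Maximum hydraulic diameter over a contour stack
#'
#' The classic AAA severity measure: the largest per-slice hydraulic diameter.
#'
#' @inheritParams diameter_profile
#' @return one-row tibble `d_max` (mm), `slice_index`, `z`.
#' @export
max_hydraulic_diameter <- function(contours) {
  prof <- diameter_profile(contours)
  i <- which.max(prof$d_h)
  tibble(d_max = prof$d_h[i], slice_index = prof$slice_index[i], z = prof$z[i])
}

#' Serialize contour tables
#'
#' CSV keeps the flat point table; JSON groups points per contour.
#' @param contours contour tibble.
#' @param path output file.
#' @export
write_contours_csv <- function(contours, path) {
  utils::write.csv(contours, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  as_tibble(utils::read.csv(path))
}

#' @rdname write_contours_csv
#' @export
write_contours_json <- function(contours, path) {
  sets <- contours |>
    dplyr::group_by(.data$slice_index, .data$contour_id) |>
    dplyr::group_map(function(g, key) {
      list(
        slice_index = key$slice_index, contour_id = key$contour_id,
        z = g$z[1], x = g$x, y = g$y
      )
    })
  jsonlite::write_json(sets, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_json <- function(path) {
  sets <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  purrr::map_dfr(sets, function(s) {
    tibble(
      slice_index = s$slice_index, z = s$z, contour_id = s$contour_id,
      x = unlist(s$x), y = unlist(s$y)
    )
  })
}

#' Plot a contour stack
#'
#' @param object contour tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot aaa_contours
#' @export
autoplot.aaa_contours <- function(object, ...) plot_contours(object)

#' @rdname autoplot.aaa_contours
#' @param contours contour tibble.
#' @export
plot_contours <- function(contours, ...) {
  ggplot2::ggplot(contours, ggplot2::aes(.data$x, .data$y,
    group = interaction(.data$slice_index, .data$contour_id),
    colour = .data$z
  )) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "z (mm)")
}
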