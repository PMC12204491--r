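#' Clamped uniform knot vector
#'
#' End knots repeated `degree + 1` times so the curve interpolates its end
#' control points; interior knots uniform on `[0, 1]`.
#'
#' @param n_ctrl number of control points (>= degree + 1).
#' @param degree spline degree `p` (>= 1).
#' @return numeric knot vector of length `n_ctrl + degree + 1`.
#' @examples
#' nurbs_knots(4, 3) # Bezier case: c(0,0,0,0,1,1,1,1)
#' @export
nurbs_knots <- function(n_ctrl, degree) {
  if (degree < 1) abort("degree must be >= 1")
  if (n_ctrl < degree + 1) abort("need at least degree + 1 control points")
  n_int <- n_ctrl - degree - 1L
  c(rep(0, degree + 1), seq_len(n_int) / (n_int + 1), rep(1, degree + 1))
}

#' B-spline basis functions (Cox-de Boor)
#'
#' `bspline_basis()` evaluates a single basis function `N_{i,p}(t)`;
#' `bspline_basis_matrix()` evaluates all of them at once and is what the
#' evaluators and fitters use. The 0/0 convention of the recursion is 0.
#'
#' @param i basis index, 0-based (0 .. n_ctrl - 1).
#' @param degree degree `p`.
#' @param t parameter values in `[0, 1]` (vectorized).
#' @param knots clamped knot vector.
#' @return `bspline_basis()`: numeric vector `N_{i,p}(t)`;
#'   `bspline_basis_matrix()`: matrix `length(t) x n_ctrl`.
#' @export
bspline_basis <- function(i, degree, t, knots) {
  bspline_basis_matrix(t, degree, knots)[, i + 1L]
}

#' @rdname bspline_basis
#' @export
bspline_basis_matrix <- function(t, degree, knots) {
  n_ctrl <- length(knots) - degree - 1L
  if (n_ctrl < 1L) abort("knot vector too short for this degree")
  tmax <- knots[length(knots)]
  m <- length(t)
  # degree 0: indicator of the half-open knot span, closed at the domain end
  N <- matrix(0, m, length(knots) - 1L)
  for (j in seq_len(length(knots) - 1L)) {
    lo <- knots[j]; hi <- knots[j + 1L]
    if (hi > lo) {
      N[, j] <- as.numeric(t >= lo & (t < hi | (t == tmax & hi == tmax)))
    }
  }
  if (degree == 0) return(N[, seq_len(n_ctrl), drop = FALSE])
  for (p in seq_len(degree)) {
    ncols <- length(knots) - p - 1L
    Np <- matrix(0, m, ncols)
    for (j in seq_len(ncols)) {
      d1 <- knots[j + p] - knots[j]
      d2 <- knots[j + p + 1L] - knots[j + 1L]
      a <- if (d1 > 0) (t - knots[j]) / d1 * N[, j] else 0
      b <- if (d2 > 0) (knots[j + p + 1L] - t) / d2 * N[, j + 1L] else 0
      Np[, j] <- a + b
    }
    N <- Np
  }
  N[, seq_len(n_ctrl), drop = FALSE]
}

#' NURBS curve objects
#'
#' A non-uniform rational B-spline curve
#' `c(t) = sum_i N_{i,p}(t) w_i P_i / sum_i N_{i,p}(t) w_i`
#' with control points `P_i`, positive weights `w_i`, degree `p` and a clamped
#' knot vector. With all weights equal the curve reduces to an ordinary
#' B-spline.
#'
#' @param control_points numeric matrix `n x 2` (mm) or data frame with
#'   `x`, `y`.
#' @param weights positive weights, recycled; default all 1.
#' @param degree degree `p` >= 1.
#' @param knots clamped knot vector; default [nurbs_knots()].
#' @return object of class `nurbs_curve`.
#' @export
nurbs_curve <- function(control_points, weights = 1, degree = 3,
                        knots = NULL) {
  if (is.data.frame(control_points)) {
    control_points <- cbind(control_points$x, control_points$y)
  }
  control_points <- as.matrix(control_points)
  n <- nrow(control_points)
  weights <- rep_len(as.numeric(weights), n)
  if (any(weights <= 0)) abort("all weights must be positive")
  if (is.null(knots)) knots <- nurbs_knots(n, degree)
  if (length(knots) != n + degree + 1L) {
    abort("knot vector length must equal n_ctrl + degree + 1")
  }
  if (is.unsorted(knots)) abort("knot vector must be non-decreasing")
  structure(
    list(
      control_points = unname(control_points), weights = weights,
      degree = as.integer(degree), knots = as.numeric(knots)
    ),
    class = "nurbs_curve"
  )
}

#' @export
print.nurbs_curve <- function(x, ...) {
  cat(sprintf(
    "<nurbs_curve> degree %d, %d control points%s\n",
    x$degree, nrow(x$control_points),
    if (all(x$weights == x$weights[1])) "" else ", non-uniform weights"
  ))
  invisible(x)
}

#' @method tidy nurbs_curve
#' @export
tidy.nurbs_curve <- function(x, ...) {
  tibble(
    index = seq_len(nrow(x$control_points)),
    x = x$control_points[, 1], y = x$control_points[, 2],
    weight = x$weights
  )
}

#' @method glance nurbs_curve
#' @export
glance.nurbs_curve <- function(x, ...) {
  tibble(
    degree = x$degree, n_ctrl = nrow(x$control_points),
    max_fit_residual = attr(x, "max_fit_residual") %||% NA_real_
  )
}

#' Evaluate a NURBS curve
#'
#' @param curve a [nurbs_curve()].
#' @param t parameter values in `[0, 1]` (vectorized).
#' @return numeric matrix `length(t) x 2` of points (mm).
#' @export
nurbs_evaluate <- function(curve, t) {
  if (any(t < -1e-12 | t > 1 + 1e-12)) abort("t must lie in [0, 1]")
  t <- pmin(pmax(t, 0), 1)
  N <- bspline_basis_matrix(t, curve$degree, curve$knots)
  Nw <- sweep(N, 2, curve$weights, `*`)
  den <- rowSums(Nw)
  (Nw %*% curve$control_points) / den
}

#' Least-squares NURBS fit to a closed contour
#'
#' Chord-length parameterization with the seam point repeated (the first
#' contour point is appended as the last data point), unit weights, clamped
#' knots; the clamped curve then starts and ends at the seam, closing the
#' loop with C0 continuity. First and last control points are pinned to the
#' seam point; interior control points solve the normal equations.
#'
#' @param contour data frame with `x`, `y` columns (ordered closed polygon,
#'   first point not repeated).
#' @param n_ctrl number of control points; default
#'   `max(8, ceiling(nrow(contour) / 10))`.
#' @param degree degree, default 3 (cubic).
#' @param params optional data-point parameters in `[0, 1]` (length
#'   `nrow(contour) + 1`, seam repeated); default chord-length.
#' @return a `nurbs_curve` with attribute `max_fit_residual` (mm); see
#'   [glance()][generics::glance].
#' @export
nurbs_fit <- function(contour, n_ctrl = NULL, degree = 3, params = NULL) {
  check_contour(contour)
  pts <- rbind(cbind(contour$x, contour$y),
               c(contour$x[1], contour$y[1]))
  m <- nrow(pts)
  if (is.null(n_ctrl)) n_ctrl <- max(8L, ceiling(nrow(contour) / 10))
  if (n_ctrl < degree + 1) abort("need n_ctrl >= degree + 1")
  if (n_ctrl > m) abort("more control points than contour points: underdetermined fit")
  if (is.null(params)) {
    seg <- sqrt(rowSums(diff(pts)^2))
    s <- c(0, cumsum(seg))
    if (s[m] <= 0) abort("degenerate contour (zero length)")
    tpar <- s / s[m]
  } else {
    if (length(params) != m) abort("params must cover every data point plus the seam")
    tpar <- params
  }
  knots <- nurbs_knots(n_ctrl, degree)
  N <- bspline_basis_matrix(tpar, degree, knots)
  # pin the two seam control points, solve for the interior
  seam <- pts[1, ]
  fixedN <- N[, c(1L, n_ctrl), drop = FALSE]
  rhs <- pts - fixedN %*% rbind(seam, seam)
  A <- N[, 2:(n_ctrl - 1L), drop = FALSE]
  AtA <- crossprod(A)
  if (rcond(AtA) < 1e-14) abort("fit system is numerically singular; reduce n_ctrl")
  interior <- solve(AtA, crossprod(A, rhs))
  cp <- rbind(seam, interior, seam)
  curve <- nurbs_curve(cp, weights = 1, degree = degree, knots = knots)
  fitted <- nurbs_evaluate(curve, tpar)
  attr(curve, "max_fit_residual") <- max(sqrt(rowSums((fitted - pts)^2)))
  curve
}

#' Apply batch control-point edits to a NURBS curve
#'
#' The file-based counterpart of interactive contour editing: each edit moves
#' one control point by `(dx, dy)` mm and may replace its weight. Edits are
#' pure (a new curve is returned) and local: by the compact support of the
#' B-spline basis, samples farther than `degree + 1` knot spans from an edited
#' control point are unchanged.
#'
#' @param curve a [nurbs_curve()].
#' @param edits data frame with columns `index` (1-based control-point index),
#'   `dx`, `dy` (mm, default 0), and optionally `new_weight` (> 0, `NA` keeps
#'   the old weight).
#' @return a new `nurbs_curve`.
#' @export
nurbs_edit <- function(curve, edits) {
  if (!inherits(curve, "nurbs_curve")) abort("`curve` must be a nurbs_curve")
  if (nrow(edits) == 0L) return(curve)
  n <- nrow(curve$control_points)
  idx <- as.integer(edits$index)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n)) {
    abort("edit index out of range")
  }
  cp <- curve$control_points
  w <- curve$weights
  dx <- if ("dx" %in% names(edits)) edits$dx else 0
  dy <- if ("dy" %in% names(edits)) edits$dy else 0
  for (r in seq_len(nrow(edits))) {
    cp[idx[r], 1] <- cp[idx[r], 1] + dx[r]
    cp[idx[r], 2] <- cp[idx[r], 2] + dy[r]
    if ("new_weight" %in% names(edits) && !is.na(edits$new_weight[r])) {
      if (edits$new_weight[r] <= 0) abort("new_weight must be positive")
      w[idx[r]] <- edits$new_weight[r]
    }
  }
  nurbs_curve(cp, weights = w, degree = curve$degree, knots = curve$knots)
}

#' Sample a NURBS curve back into a contour
#'
#' Samples the curve at uniform parameters (seam duplicate dropped), then
#' arc-length resamples with the shared start convention so the result plugs
#' straight back into the mask/mesh pipeline.
#'
#' @param curve a [nurbs_curve()].
#' @param n_samples output point count (>= 8).
#' @param slice_index,z metadata carried onto the output rows.
#' @return contour tibble with `slice_index`, `z`, `contour_id`, `x`, `y`.
#' @export
nurbs_to_contour <- function(curve, n_samples = 256, slice_index = 1L, z = 0) {
  if (n_samples < 8) abort("need n_samples >= 8")
  tt <- seq(0, 1, length.out = 4L * n_samples + 1L)[-(4L * n_samples + 1L)]
  pts <- nurbs_evaluate(curve, tt)
  raw <- tibble(
    slice_index = as.integer(slice_index), z = z, contour_id = 1L,
    x = pts[, 1], y = pts[, 2]
  )
  resample_contour(raw, n_samples)
}

#' Serialize NURBS curves as JSON
#'
#' @param curve a [nurbs_curve()] (or named list of them).
#' @param path output file.
#' @export
write_nurbs_json <- function(curve, path) {
  ser <- function(cv) list(
    control_points = unname(apply(cv$control_points, 1, as.numeric,
                                  simplify = FALSE)),
    weights = cv$weights, degree = cv$degree, knots = cv$knots
  )
  obj <- if (inherits(curve, "nurbs_curve")) ser(curve) else lapply(curve, ser)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nurbs_json
#' @export
read_nurbs_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  des <- function(o) nurbs_curve(
    do.call(rbind, if (is.list(o$control_points)) o$control_points else list(o$control_points)),
    weights = o$weights, degree = o$degree, knots = o$knots
  )
  if (!is.null(obj$degree)) des(obj) else lapply(obj, des)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
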