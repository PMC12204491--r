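#' Oriented triangular surface mesh
#'
#' The geometry container for the stress solver: vertices in mm, triangles as
#' 1-based vertex index triples with consistent outward winding, and two
#' tagged boundary rings (proximal and distal vertex index sets) where the
#' wall is held fixed. A lofted vessel is an open tube: Euler characteristic
#' `V - E + F = 0` with exactly two boundary loops.
#'
#' @param vertices numeric matrix `V x 3` (mm).
#' @param triangles integer matrix `F x 3`, 1-based.
#' @param proximal,distal integer vectors of boundary-ring vertex indices
#'   (may be empty for closed surfaces).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, proximal = integer(),
                         distal = integer()) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3) abort("vertices must be V x 3")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices)) {
    abort("triangle indices out of range")
  }
  structure(
    list(
      vertices = unname(vertices), triangles = unname(triangles),
      proximal = as.integer(proximal), distal = as.integer(distal)
    ),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %d vertices, %d triangles, chi = %d; %d proximal / %d distal boundary vertices\n",
    nrow(x$vertices), nrow(x$triangles), mesh_euler_characteristic(x),
    length(x$proximal), length(x$distal)
  ))
  invisible(x)
}

mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Mesh invariants: Euler characteristic, area, normals, orientation
#'
#' @param mesh a [surface_mesh()].
#' @return `mesh_euler_characteristic()`: integer `V - E + F`;
#'   `mesh_area()`: total area in mm^2; `mesh_face_normals()`: `F x 3` unit
#'   normals; `mesh_face_areas()`: per-face areas (mm^2);
#'   `mesh_boundary_loops()`: list of vertex-index loops.
#' @export
mesh_euler_characteristic <- function(mesh) {
  e <- mesh_edges(mesh)
  nrow(mesh$vertices) - nrow(unique(e)) + nrow(mesh$triangles)
}

tri_cross <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' @rdname mesh_euler_characteristic
#' @export
mesh_face_areas <- function(mesh) {
  cr <- tri_cross(mesh)
  sqrt(rowSums(cr^2)) / 2
}

#' @rdname mesh_euler_characteristic
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' @rdname mesh_euler_characteristic
#' @export
mesh_face_normals <- function(mesh) {
  cr <- tri_cross(mesh)
  nr <- sqrt(rowSums(cr^2))
  if (any(nr <= 0)) abort("mesh contains a degenerate (zero-area) triangle")
  cr / nr
}

#' @rdname mesh_euler_characteristic
#' @export
mesh_boundary_loops <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  be <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  if (nrow(be) == 0L) return(list())
  # walk boundary edges into loops
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  visited <- character()
  loops <- list()
  remaining <- be
  while (nrow(remaining) > 0L) {
    loop <- c(remaining[1, 1], remaining[1, 2])
    repeat {
      cur <- loop[length(loop)]
      prev <- loop[length(loop) - 1L]
      nxt <- setdiff(adj[[as.character(cur)]], prev)
      nxt <- nxt[!nxt %in% loop[-1L]]
      if (length(nxt) == 0L || nxt[1] == loop[1]) break
      loop <- c(loop, nxt[1])
    }
    loops[[length(loops) + 1L]] <- loop
    inloop <- (remaining[, 1] %in% loop) & (remaining[, 2] %in% loop)
    remaining <- remaining[!inloop, , drop = FALSE]
  }
  loops
}

mesh_signed_volume_capped <- function(mesh) {
  # cap each boundary loop with a centroid fan, then divergence-theorem volume
  v <- mesh$vertices
  tr <- mesh$triangles
  loops <- mesh_boundary_loops(mesh)
  for (loop in loops) {
    centroid <- colMeans(v[loop, , drop = FALSE])
    ci <- nrow(v) + 1L
    v <- rbind(v, centroid)
    # choose the fan winding that keeps the edge direction opposite to the
    # boundary edge's use in the open surface (so the cap closes it)
    for (k in seq_along(loop)) {
      a <- loop[k]; b <- loop[if (k == length(loop)) 1L else k + 1L]
      # find how (a,b) is used in existing triangles
      used_ab <- any(
        (tr[, 1] == a & tr[, 2] == b) | (tr[, 2] == a & tr[, 3] == b) |
          (tr[, 3] == a & tr[, 1] == b)
      )
      tri <- if (used_ab) c(b, a, ci) else c(a, b, ci)
      tr <- rbind(tr, tri)
    }
  }
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  sum(
    a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
    a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  ) / 6
}

flip_mesh <- function(mesh) {
  mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}

#' Loft a contour stack into an open tube mesh
#'
#' Each contour is resampled to `n_circ` points with the shared start-point
#' convention of [resample_contour()]; consecutive rings are then aligned by
#' the cyclic rotation minimizing total inter-ring chord length (guards
#' against twist on tortuous centerlines) and connected by `2 * n_circ`
#' triangles per ring pair, each quad split along its shorter diagonal. The
#' first ring is tagged proximal, the last distal, and the winding is flipped
#' if needed so normals point outward (positive signed volume after capping).
#'
#' @param contours contour tibble covering >= 2 slices with distinct `z`; one
#'   contour per slice (largest is taken if several).
#' @param n_circ circumferential resolution (>= 8).
#' @return a [surface_mesh()].
#' @export
loft_contours <- function(contours, n_circ = 64) {
  if (n_circ < 8) abort("need n_circ >= 8")
  if (nrow(contours) == 0L) abort("no contours supplied")
  keep <- contours |>
    dplyr::group_by(.data$slice_index, .data$contour_id) |>
    dplyr::summarise(
      z = .data$z[1], area = abs(shoelace_area(.data$x, .data$y)),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$slice_index) |>
    dplyr::slice_max(.data$area, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (nrow(keep) < 2L) abort("lofting needs contours on at least 2 slices")
  if (anyDuplicated(keep$z)) abort("contours on duplicate z planes")
  keep <- keep[order(keep$z), ]
  rings <- purrr::pmap(keep, function(slice_index, contour_id, z, area) {
    piece <- contours[contours$slice_index == slice_index &
                        contours$contour_id == contour_id, ]
    rc <- resample_contour(piece, n_circ)
    cbind(rc$x, rc$y, z)
  })
  # cyclic alignment pass
  for (k in 2:length(rings)) {
    prev <- rings[[k - 1]]; cur <- rings[[k]]
    costs <- vapply(0:(n_circ - 1L), function(off) {
      idx <- ((seq_len(n_circ) - 1L + off) %% n_circ) + 1L
      sum(sqrt(rowSums((cur[idx, , drop = FALSE] - prev)^2)))
    }, 0)
    best <- which.min(costs) - 1L
    if (best > 0L) {
      idx <- ((seq_len(n_circ) - 1L + best) %% n_circ) + 1L
      rings[[k]] <- cur[idx, , drop = FALSE]
    }
  }
  nr <- length(rings)
  vertices <- do.call(rbind, rings)
  tris <- matrix(0L, 0, 3)
  for (k in seq_len(nr - 1L)) {
    base0 <- (k - 1L) * n_circ
    base1 <- k * n_circ
    for (j in seq_len(n_circ)) {
      jn <- if (j == n_circ) 1L else j + 1L
      a <- base0 + j; b <- base0 + jn
      c2 <- base1 + j; d <- base1 + jn
      # split quad (a, b, d, c2) along its shorter diagonal
      dag_ad <- sum((vertices[a, ] - vertices[d, ])^2)
      dag_bc <- sum((vertices[b, ] - vertices[c2, ])^2)
      if (dag_ad <= dag_bc) {
        tris <- rbind(tris, c(a, b, d), c(a, d, c2))
      } else {
        tris <- rbind(tris, c(a, b, c2), c(b, d, c2))
      }
    }
  }
  mesh <- surface_mesh(vertices, tris,
    proximal = seq_len(n_circ),
    distal = (nr - 1L) * n_circ + seq_len(n_circ)
  )
  areas <- mesh_face_areas(mesh)
  if (any(areas < 1e-12)) abort("lofting produced a degenerate triangle")
  if (mesh_signed_volume_capped(mesh) < 0) mesh <- flip_mesh(mesh)
  mesh
}

#' Hydraulic diameter profile from a lofted mesh
#'
#' Cross-sections the mesh at its vertex rings (lofted meshes keep rings at
#' the source slice z planes) and computes `4A/P` per ring — the mesh-based
#' counterpart of [diameter_profile()] on raw contours.
#'
#' @param mesh a lofted [surface_mesh()] produced by [loft_contours()].
#' @return tibble `z`, `d_h`.
#' @export
mesh_diameter_profile <- function(mesh) {
  zs <- sort(unique(round(mesh$vertices[, 3], 9)))
  purrr::map_dfr(zs, function(z) {
    ring <- mesh$vertices[abs(mesh$vertices[, 3] - z) < 1e-8, , drop = FALSE]
    if (nrow(ring) < 3) return(tibble())
    ct <- tibble(x = ring[, 1], y = ring[, 2])
    tibble(z = z, d_h = hydraulic_diameter(ct))
  })
}

# ---- mesh I/O -------------------------------------------------------------

#' Read and write surface meshes (ASCII PLY, ASCII/binary STL, JSON)
#'
#' PLY and JSON round-trip boundary tags (PLY via a per-vertex integer
#' property `boundary`: 0 interior, 1 proximal, 2 distal); STL stores bare
#' triangle soup, so tags are lost and vertices are merged on read.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @param face_scalar optional numeric per-face values written as a PLY face
#'   property `quality` (e.g. first principal stress for visualization).
#' @return readers return a [surface_mesh()].
#' @export
write_mesh_ply <- function(mesh, path, face_scalar = NULL) {
  v <- mesh$vertices; tr <- mesh$triangles
  tags <- integer(nrow(v))
  tags[mesh$proximal] <- 1L
  tags[mesh$distal] <- 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment aaastress surface mesh",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    "property int boundary",
    sprintf("element face %d", nrow(tr)),
    "property list uchar int vertex_indices",
    if (!is.null(face_scalar)) "property double quality",
    "end_header"
  ), con)
  writeLines(sprintf("%.10g %.10g %.10g %d", v[, 1], v[, 2], v[, 3], tags), con)
  if (is.null(face_scalar)) {
    writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  } else {
    writeLines(sprintf(
      "3 %d %d %d %.10g",
      tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L, face_scalar
    ), con)
  }
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")[1]
  header <- lines[seq_len(endh)]
  if (!any(grepl("^format ascii", header))) abort("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  vl <- lines[endh + seq_len(nv)]
  fl <- lines[endh + nv + seq_len(nf)]
  vparts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), as.numeric))
  v <- vparts[, 1:3, drop = FALSE]
  tags <- if (ncol(vparts) >= 4) as.integer(vparts[, 4]) else integer(nv)
  fparts <- do.call(rbind, lapply(strsplit(fl, "\\s+"), as.numeric))
  tr <- fparts[, 2:4, drop = FALSE] + 1L
  surface_mesh(v, tr, proximal = which(tags == 1L), distal = which(tags == 2L))
}

#' @rdname write_mesh_ply
#' @param binary write binary little-endian STL (default) or the ASCII dialect.
#' @export
write_mesh_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; tr <- mesh$triangles
  nrm <- mesh_face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("aaastress binary STL", width = -80)), con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(c(
        nrm[i, ], t(v[tr[i, ], , drop = FALSE])
      )), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid aaastress", con)
    for (i in seq_len(nrow(tr))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[tr[i, ], 1], v[tr[i, ], 2], v[tr[i, ], 3]),
        "    endloop", "  endfacet"
      ), con)
    }
    writeLines("endsolid aaastress", con)
  }
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_stl <- function(path) {
  head <- readBin(path, "raw", n = 6)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    length(grep("facet", readLines(path, n = 20, warn = FALSE))) > 0
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(p) as.numeric(p[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    coords <- matrix(NA_real_, 3 * nt, 3)
    for (i in seq_len(nt)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      invisible(readBin(con, "raw", n = 2))
      coords[3 * (i - 1) + 1:3, ] <- matrix(rec[4:12], 3, byrow = TRUE)
    }
  }
  key <- apply(round(coords, 7), 1, paste, collapse = " ")
  uk <- unique(key)
  idx <- match(key, uk)
  v <- coords[!duplicated(key), , drop = FALSE]
  tr <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(v, tr)
}

#' @rdname write_mesh_ply
#' @export
write_mesh_json <- function(mesh, path) {
  jsonlite::write_json(
    list(
      vertices = mesh$vertices, triangles = mesh$triangles,
      proximal = mesh$proximal, distal = mesh$distal
    ),
    path, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  surface_mesh(o$vertices, o$triangles,
               proximal = o$proximal %||% integer(),
               distal = o$distal %||% integer())
}
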