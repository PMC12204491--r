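#' Convert intraluminal pressure from mmHg to stress units (N/cm^2)
#'
#' `1 mmHg = 133.322 Pa = 133.322e-4 N/cm^2`; all stresses the solver reports
#' are in N/cm^2, the conventional unit for aortic wall stress.
#'
#' @param p_mmHg pressure in mmHg (>= 0).
#' @return pressure in N/cm^2.
#' @examples
#' pressure_to_stress_units(93.3) # mean arterial pressure -> 1.2439 N/cm^2
#' @export
pressure_to_stress_units <- function(p_mmHg) {
  if (any(p_mmHg < 0)) abort("pressure must be non-negative")
  p_mmHg * 133.322 * 1e-4
}

#' Local covariant frame of a mesh triangle
#'
#' The element's parameterization maps the reference triangle
#' `(0,0), (1,0), (0,1)` linearly onto the physical triangle, so the covariant
#' basis vectors are the edge vectors `g_1 = v2 - v1`, `g_2 = v3 - v1`, the
#' metric is `g_ab = g_a . g_b` with determinant `g`, and the unit normal
#' follows the winding: `n = g_1 x g_2 / |g_1 x g_2|`.
#'
#' @param tri numeric `3 x 3` matrix, one vertex per row (mm).
#' @return list with `g1`, `g2`, `normal`, `metric` (2x2), `g` (determinant),
#'   `sqrt_g`, `area` (mm^2).
#' @export
element_frame <- function(tri) {
  tri <- as.matrix(tri)
  g1 <- tri[2, ] - tri[1, ]
  g2 <- tri[3, ] - tri[1, ]
  cr <- c(
    g1[2] * g2[3] - g1[3] * g2[2],
    g1[3] * g2[1] - g1[1] * g2[3],
    g1[1] * g2[2] - g1[2] * g2[1]
  )
  sqrt_g <- sqrt(sum(cr^2))
  if (sqrt_g <= 0) abort("degenerate (zero-area) triangle")
  metric <- matrix(
    c(sum(g1 * g1), sum(g1 * g2), sum(g1 * g2), sum(g2 * g2)), 2, 2
  )
  list(
    g1 = g1, g2 = g2, normal = cr / sqrt_g, metric = metric,
    g = det(metric), sqrt_g = sqrt_g, area = sqrt_g / 2
  )
}

# per-vertex orthonormal tangent frames from area-weighted vertex normals
node_frames <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  cr <- tri_cross(mesh) # face normal * 2A
  nrm <- matrix(0, nrow(v), 3)
  for (c3 in 1:3) {
    for (j in 1:3) {
      agg <- rowsum(cr[, j], tr[, c3])
      idx <- as.integer(rownames(agg))
      nrm[idx, j] <- nrm[idx, j] + agg[, 1]
    }
  }
  len <- sqrt(rowSums(nrm^2))
  if (any(len <= 0)) abort("isolated or fully degenerate vertex in mesh")
  nrm <- nrm / len
  # deterministic tangent: project the global axis least aligned with n
  axis_pick <- max.col(-abs(nrm), ties.method = "first")
  a <- diag(3)[axis_pick, , drop = FALSE]
  e1 <- a - nrm * rowSums(a * nrm)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(
    nrm[, 2] * e1[, 3] - nrm[, 3] * e1[, 2],
    nrm[, 3] * e1[, 1] - nrm[, 1] * e1[, 3],
    nrm[, 1] * e1[, 2] - nrm[, 2] * e1[, 1]
  )
  list(normal = nrm, e1 = e1, e2 = e2)
}

#' Define an inverse membrane equilibrium problem
#'
#' Wall stress in a pressurized membrane is statically determinate: the
#' equilibrium equation `(1/sqrt(g)) (sqrt(g) h sigma^{ab} g_a)_{,b} + p n = 0`
#' fixes the Cauchy stress from the deformed geometry, the wall thickness and
#' the intraluminal pressure alone — no material properties. The mesh is taken
#' as the deformed (in vivo, pressurized) configuration; pressure acts
#' outwards along the surface normal on the internal faces; the proximal and
#' distal boundary rings are fixed.
#'
#' @param mesh a [surface_mesh()] with tagged boundary rings.
#' @param thickness uniform wall thickness `h` in mm (default 1.5, the
#'   standard AAA wall assumption).
#' @param pressure intraluminal pressure in mmHg (default 93.3, mean arterial
#'   pressure).
#' @param fixed optional explicit vertex index set to fix; defaults to the
#'   union of the mesh's proximal and distal rings.
#' @return object of class `membrane_problem`.
#' @export
membrane_problem <- function(mesh, thickness = 1.5, pressure = 93.3,
                             fixed = NULL) {
  if (!inherits(mesh, "surface_mesh")) abort("`mesh` must be a surface_mesh")
  if (thickness <= 0) abort("thickness must be positive (mm)")
  if (pressure < 0) abort("pressure must be non-negative (mmHg)")
  fixed <- if (is.null(fixed)) union(mesh$proximal, mesh$distal) else as.integer(fixed)
  if (length(fixed) > 0 && (min(fixed) < 1 || max(fixed) > nrow(mesh$vertices))) {
    abort("fixed node indices out of range")
  }
  structure(
    list(mesh = mesh, thickness = thickness, pressure = pressure,
         fixed = sort(unique(fixed))),
    class = "membrane_problem"
  )
}

#' @export
print.membrane_problem <- function(x, ...) {
  cat(sprintf(
    "<membrane_problem> %d vertices / %d faces, h = %g mm, p = %g mmHg, %d fixed nodes\n",
    nrow(x$mesh$vertices), nrow(x$mesh$triangles), x$thickness, x$pressure,
    length(x$fixed)
  ))
  invisible(x)
}

# Assemble the linear Galerkin system K s = f in the nodal stress unknowns.
#
# Unknown layout: 3 dofs per vertex — components (s11, s22, s12) of the
# symmetric tangent stress tensor in the vertex's orthonormal tangent frame,
# in N/cm^2. Per element the nodal tensors are projected into the element's
# contravariant basis, interpolated linearly, and tested against P1 shape
# functions; equilibrium rows at fixed nodes are dropped by the caller.
assemble_membrane_system <- function(problem) {
  mesh <- problem$mesh
  v <- mesh$vertices
  tr <- mesh$triangles
  h <- problem$thickness
  p <- pressure_to_stress_units(problem$pressure)
  nf <- node_frames(mesh)
  nv <- nrow(v)
  nel <- nrow(tr)
  dphi <- rbind(c(-1, -1), c(1, 0), c(0, 1)) # d phi_a / d xi_alpha

  ntrip <- nel * 3L * 3L * 9L
  ti <- integer(ntrip); tj <- integer(ntrip); txv <- numeric(ntrip)
  f <- numeric(3L * nv)
  pos <- 0L
  for (e in seq_len(nel)) {
    vi <- tr[e, ]
    fr <- element_frame(v[vi, , drop = FALSE])
    G <- fr$metric
    Gi <- solve(G)
    gd1 <- Gi[1, 1] * fr$g1 + Gi[1, 2] * fr$g2 # dual basis g^1
    gd2 <- Gi[2, 1] * fr$g1 + Gi[2, 2] * fr$g2 # g^2
    A <- fr$area
    # pressure load: A p n / 3 to each vertex
    for (a in 1:3) {
      rows <- 3L * (vi[a] - 1L) + 1:3
      f[rows] <- f[rows] + p * A * fr$normal / 3
    }
    gB <- rbind(fr$g1, fr$g2) # covariant, rows alpha
    gD <- rbind(gd1, gd2)     # dual, rows alpha
    for (b in 1:3) {
      nb <- vi[b]
      e1b <- nf$e1[nb, ]; e2b <- nf$e2[nb, ]
      # projections of the node-frame dyads onto the dual basis
      u1 <- c(sum(gd1 * e1b), sum(gd2 * e1b)) # g^alpha . e1
      u2 <- c(sum(gd1 * e2b), sum(gd2 * e2b)) # g^alpha . e2
      # sig[m, alpha, beta] = d sigma^{alpha beta} / d s_m
      sig <- array(0, c(3, 2, 2))
      sig[1, , ] <- outer(u1, u1)
      sig[2, , ] <- outer(u2, u2)
      sig[3, , ] <- outer(u1, u2) + outer(u2, u1)
      for (a in 1:3) {
        # block(i, m) = (h A / 3) sum_{alpha beta} sig[m,a,b] dphi[a,alpha] g_beta[i]
        blk <- matrix(0, 3, 3)
        for (m in 1:3) {
          w <- dphi[a, 1] * (sig[m, 1, 1] * gB[1, ] + sig[m, 1, 2] * gB[2, ]) +
               dphi[a, 2] * (sig[m, 2, 1] * gB[1, ] + sig[m, 2, 2] * gB[2, ])
          blk[, m] <- (h * A / 3) * w
        }
        rows <- 3L * (vi[a] - 1L) + 1:3
        cols <- 3L * (vi[b] - 1L) + 1:3
        idx <- pos + 1:9
        ti[idx] <- rep(rows, times = 3)
        tj[idx] <- rep(cols, each = 3)
        txv[idx] <- as.numeric(blk)
        pos <- pos + 9L
      }
    }
  }
  K <- Matrix::sparseMatrix(i = ti, j = tj, x = txv, dims = c(3L * nv, 3L * nv))
  free_rows <- rep(TRUE, 3L * nv)
  if (length(problem$fixed) > 0) {
    free_rows[as.vector(outer(1:3, 3L * (problem$fixed - 1L), `+`))] <- FALSE
  }
  list(K = K, f = f, free_rows = free_rows, node_frames = nf)
}

#' Equilibrium residual for a given nodal stress state
#'
#' Evaluates the Galerkin weak-form residual of the membrane equilibrium
#' equation at the supplied nodal stress unknowns, with the rows belonging to
#' fixed proximal/distal nodes removed. A stress state satisfying discrete
#' equilibrium gives a (near-)zero vector.
#'
#' @param problem a [membrane_problem()].
#' @param dofs numeric vector of length `3 * n_vertices`: per vertex
#'   `(s11, s22, s12)` in the vertex tangent frame, N/cm^2.
#' @return residual vector (one entry per free node and spatial direction).
#' @export
membrane_residual <- function(problem, dofs) {
  sys <- assemble_membrane_system(problem)
  if (length(dofs) != ncol(sys$K)) {
    abort(sprintf("dofs must have length %d (3 per vertex)", ncol(sys$K)))
  }
  as.numeric((sys$K %*% dofs - sys$f)[sys$free_rows])
}

#' Solve the inverse membrane problem for the wall stress field
#'
#' Newton iteration on the assembled equilibrium system (which is linear in
#' the stress unknowns for a fixed deformed geometry, so the iteration
#' converges in one step); the free-row system is solved in the regularized
#' least-squares sense (Tikhonov weight `1e-10` times the diagonal scale) to
#' guard the rank deficiency introduced by removing the fixed-ring rows.
#' Nodal stresses are then interpolated to element centroids, converted to a
#' local orthonormal frame through the metric, and eigendecomposed into
#' physical principal stresses `sigma1 >= sigma2`.
#'
#' @param problem a [membrane_problem()].
#' @param tol relative residual convergence tolerance (default 1e-8).
#' @param max_iter Newton iteration cap (default 100).
#' @param smoothing relative weight of the transported-tensor smoothness
#'   penalty that suppresses the checkerboard modes of the equal-order nodal
#'   interpolation (default 0.1 of the normal-equation diagonal scale; 0
#'   disables). The penalty vanishes on covariantly constant stress fields,
#'   so it does not bias smooth solutions.
#' @return object of class `stress_field`: a tibble with one row per element
#'   (`element`, centroid `cx, cy, cz`, `area` in mm^2, contravariant
#'   components `s11, s22, s12`, principal stresses `sigma1, sigma2` in
#'   N/cm^2, and `boundary` flagging elements touching a fixed node), with the
#'   solver state in attributes. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] / [biomech_params()].
#' @export
solve_membrane_stress <- function(problem, tol = 1e-8, max_iter = 100,
                                  smoothing = 0.1) {
  mesh <- problem$mesh
  loops <- mesh_boundary_loops(mesh)
  if (length(problem$fixed) > 0 && length(loops) < 2) {
    abort("mesh must carry two boundary rings for a fixed-end membrane solve")
  }
  sys <- assemble_membrane_system(problem)
  A <- sys$K[sys$free_rows, , drop = FALSE]
  b <- sys$f[sys$free_rows]
  AtA <- Matrix::crossprod(A)
  Atb <- as.numeric(Matrix::crossprod(A, b))
  dscale <- Matrix::diag(AtA)
  lambda <- 1e-10 * mean(dscale[dscale > 0])
  # ridge on the tensor Frobenius norm (shear dof counts twice), so the
  # minimum-norm choice on unconstrained modes is frame-independent
  reg <- AtA + lambda * Matrix::Diagonal(ncol(A), rep(c(1, 1, 2), ncol(A) / 3))
  if (smoothing > 0) {
    # damp the oscillatory near-null modes of the equal-order nodal stress
    # interpolation: small penalty on the edge-wise difference of the
    # physical stress tensors after parallel transport across the edge
    # (the neighbour's tangent plane is rotated onto the node's before
    # differencing). The penalty vanishes on covariantly constant fields
    # such as the Laplace solution and is equivariant under rigid motions.
    ed <- unique(mesh_edges(mesh))
    nv <- nrow(mesh$vertices)
    nf <- sys$node_frames
    sym6 <- function(D) {
      s2 <- sqrt(2)
      c(D[1, 1], D[2, 2], D[3, 3], s2 * D[1, 2], s2 * D[1, 3], s2 * D[2, 3])
    }
    # 6x3 map from (s11, s22, s12) at node i to symmetric-tensor components,
    # with the node frame optionally rotated by R (parallel transport)
    tens_block <- function(i, R = NULL) {
      e1 <- nf$e1[i, ]; e2 <- nf$e2[i, ]
      if (!is.null(R)) { e1 <- as.numeric(R %*% e1); e2 <- as.numeric(R %*% e2) }
      cbind(
        sym6(outer(e1, e1)), sym6(outer(e2, e2)),
        sym6(outer(e1, e2) + outer(e2, e1))
      )
    }
    rot_between <- function(a, b) {
      # minimal rotation taking unit vector a onto unit vector b (Rodrigues)
      v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
      cth <- sum(a * b)
      s2 <- sum(v^2)
      if (s2 < 1e-24) {
        if (cth > 0) return(diag(3))
        # antipodal normals: fall back to identity (degenerate mesh)
        return(diag(3))
      }
      vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      diag(3) + vx + vx %*% vx * ((1 - cth) / s2)
    }
    ne <- nrow(ed)
    ti2 <- integer(36L * ne); tj2 <- integer(36L * ne); tx2 <- numeric(36L * ne)
    pos2 <- 0L
    for (q in seq_len(ne)) {
      i <- ed[q, 1]; j <- ed[q, 2]
      rows <- 6L * (q - 1L) + 1:6
      Rj <- rot_between(nf$normal[j, ], nf$normal[i, ])
      for (bb in list(list(i, 1, NULL), list(j, -1, Rj))) {
        cols <- 3L * (bb[[1]] - 1L) + 1:3
        idx <- pos2 + 1:18
        ti2[idx] <- rep(rows, times = 3)
        tj2[idx] <- rep(cols, each = 6)
        tx2[idx] <- bb[[2]] * as.numeric(tens_block(bb[[1]], bb[[3]]))
        pos2 <- pos2 + 18L
      }
    }
    P <- Matrix::sparseMatrix(i = ti2, j = tj2, x = tx2,
                              dims = c(6L * ne, 3L * nv))
    PtP <- Matrix::crossprod(P)
    mu <- smoothing * mean(dscale[dscale > 0]) / mean(Matrix::diag(PtP))
    reg <- reg + mu * PtP
  }
  bnorm <- sqrt(sum(Atb^2))
  ref <- max(bnorm, 1e-300)
  s <- numeric(ncol(A))
  iter <- 0L
  relres <- Inf
  repeat {
    iter <- iter + 1L
    grad <- as.numeric(reg %*% s) - Atb
    relres <- sqrt(sum(grad^2)) / ref
    if (relres < tol || iter > max_iter) break
    ds <- as.numeric(Matrix::solve(reg, -grad))
    s <- s + ds
  }
  if (relres >= tol && bnorm > 0) {
    abort(sprintf(
      "membrane solve did not converge: relative residual %.3e after %d iterations",
      relres, iter - 1L
    ))
  }

  # centroid evaluation and principal stresses
  v <- mesh$vertices
  tr <- mesh$triangles
  nf <- sys$node_frames
  nel <- nrow(tr)
  out <- matrix(0, nel, 10)
  fixed_set <- problem$fixed
  for (e in seq_len(nel)) {
    vi <- tr[e, ]
    fr <- element_frame(v[vi, , drop = FALSE])
    Gi <- solve(fr$metric)
    gd1 <- Gi[1, 1] * fr$g1 + Gi[1, 2] * fr$g2
    gd2 <- Gi[2, 1] * fr$g1 + Gi[2, 2] * fr$g2
    # centroid value of the interpolated contravariant components
    s11 <- 0; s22 <- 0; s12 <- 0
    for (b in 1:3) {
      nb <- vi[b]
      sb <- s[3L * (nb - 1L) + 1:3]
      e1b <- nf$e1[nb, ]; e2b <- nf$e2[nb, ]
      u1 <- c(sum(gd1 * e1b), sum(gd2 * e1b))
      u2 <- c(sum(gd1 * e2b), sum(gd2 * e2b))
      sab <- sb[1] * outer(u1, u1) + sb[2] * outer(u2, u2) +
        sb[3] * (outer(u1, u2) + outer(u2, u1))
      s11 <- s11 + sab[1, 1] / 3
      s22 <- s22 + sab[2, 2] / 3
      s12 <- s12 + (sab[1, 2] + sab[2, 1]) / 6
    }
    # physical tensor in an orthonormal element frame
    S <- s11 * outer(fr$g1, fr$g1) + s22 * outer(fr$g2, fr$g2) +
      s12 * (outer(fr$g1, fr$g2) + outer(fr$g2, fr$g1))
    eo1 <- fr$g1 / sqrt(sum(fr$g1^2))
    eo2 <- c(
      fr$normal[2] * eo1[3] - fr$normal[3] * eo1[2],
      fr$normal[3] * eo1[1] - fr$normal[1] * eo1[3],
      fr$normal[1] * eo1[2] - fr$normal[2] * eo1[1]
    )
    t11 <- sum(eo1 * (S %*% eo1)); t22 <- sum(eo2 * (S %*% eo2))
    t12 <- sum(eo1 * (S %*% eo2))
    tr2 <- (t11 + t22) / 2
    dd <- sqrt(((t11 - t22) / 2)^2 + t12^2)
    centroid <- colMeans(v[vi, , drop = FALSE])
    out[e, ] <- c(
      centroid, fr$area, s11, s22, s12, tr2 + dd, tr2 - dd,
      as.numeric(any(vi %in% fixed_set))
    )
  }
  field <- tibble(
    element = seq_len(nel),
    cx = out[, 1], cy = out[, 2], cz = out[, 3], area = out[, 4],
    s11 = out[, 5], s22 = out[, 6], s12 = out[, 7],
    sigma1 = out[, 8], sigma2 = out[, 9],
    boundary = out[, 10] > 0
  )
  structure(
    field,
    class = c("stress_field", class(field)),
    problem = problem,
    dofs = s,
    residual = relres,
    iterations = iter - 1L
  )
}

#' @method tidy stress_field
#' @export
tidy.stress_field <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stress_field")
  attr(out, "problem") <- NULL
  attr(out, "dofs") <- NULL
  attr(out, "residual") <- NULL
  attr(out, "iterations") <- NULL
  out
}

#' @method glance stress_field
#' @export
glance.stress_field <- function(x, ...) {
  dplyr::bind_cols(
    biomech_params(x),
    tibble(
      n_elements = nrow(x),
      residual = attr(x, "residual"),
      iterations = attr(x, "iterations")
    )
  )
}

#' Biomechanical summary parameters of a wall stress field
#'
#' The five standard AAA stress descriptors, all on the first principal
#' stress `sigma1` and in N/cm^2: peak wall stress (PWS, the maximum), 99th
#' and 75th percentile wall stress, mean wall stress (unweighted over
#' elements), and spatially averaged wall stress (SAWS, the area-weighted
#' element mean).
#'
#' @param field a `stress_field` from [solve_membrane_stress()], or any data
#'   frame with `sigma1` and `area` columns.
#' @param area_weighted also area-weight the percentile and mean parameters
#'   (default `FALSE`: only SAWS is area-weighted).
#' @return one-row tibble `peak_wall_stress`, `p99`, `p75`, `mean_stress`,
#'   `saws`.
#' @examples
#' biomech_params(tibble::tibble(sigma1 = c(1, 3), area = c(3, 1)))
#' @export
biomech_params <- function(field, area_weighted = FALSE) {
  if (nrow(field) == 0L) abort("empty stress field")
  s1 <- field$sigma1
  a <- field$area
  saws <- sum(s1 * a) / sum(a)
  if (isTRUE(area_weighted)) {
    ord <- order(s1)
    cw <- cumsum(a[ord]) / sum(a)
    wq <- function(q) s1[ord][which(cw >= q)[1]]
    tibble(
      peak_wall_stress = max(s1), p99 = wq(0.99), p75 = wq(0.75),
      mean_stress = saws, saws = saws
    )
  } else {
    qs <- unname(quantile(s1, c(0.99, 0.75), type = 7))
    tibble(
      peak_wall_stress = max(s1), p99 = qs[1], p75 = qs[2],
      mean_stress = mean(s1), saws = saws
    )
  }
}

#' Graph (ring) distance of each vertex from the fixed boundary
#'
#' Breadth-first distance in the vertex adjacency graph from the given seed
#' set; used to select elements away from the fixed rings, where the membrane
#' solution is free of boundary effects.
#'
#' @param mesh a [surface_mesh()].
#' @param from seed vertex indices (default: proximal + distal rings).
#' @return integer vector, one entry per vertex (`Inf` if unreachable).
#' @export
mesh_ring_distance <- function(mesh, from = NULL) {
  if (is.null(from)) from <- union(mesh$proximal, mesh$distal)
  nv <- nrow(mesh$vertices)
  e <- unique(mesh_edges(mesh))
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  dist <- rep(Inf, nv)
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Write stress results
#'
#' `write_stress_csv()` writes the per-element table;
#' `write_stress_ply()` writes the mesh with `sigma1` as a per-face scalar
#' (PLY `quality` property) for visualization;
#' `write_biomech_json()` writes the five-parameter report.
#'
#' @param field a `stress_field`.
#' @param path output file.
#' @export
write_stress_csv <- function(field, path) {
  utils::write.csv(tidy(field), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stress_csv
#' @export
write_stress_ply <- function(field, path) {
  problem <- attr(field, "problem")
  write_mesh_ply(problem$mesh, path, face_scalar = field$sigma1)
  invisible(path)
}

#' @rdname write_stress_csv
#' @export
write_biomech_json <- function(field, path) {
  jsonlite::write_json(
    as.list(biomech_params(field)), path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Plot a wall stress field
#'
#' Flattens the surface to a cylindrical unwrap (angle vs z) coloured by
#' first principal stress — a quick diagnostic view, not a 3D render.
#'
#' @param object,field a `stress_field`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot stress_field
#' @export
autoplot.stress_field <- function(object, ...) plot_stress_field(object)

#' @rdname autoplot.stress_field
#' @export
plot_stress_field <- function(field, ...) {
  df <- tidy(field)
  df$theta <- atan2(df$cy - mean(df$cy), df$cx - mean(df$cx))
  ggplot2::ggplot(df, ggplot2::aes(.data$theta, .data$cz, colour = .data$sigma1)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      x = "circumferential angle (rad)", y = "z (mm)",
      colour = expression(sigma[1] ~ "(N/cm"^2 * ")")
    )
}
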