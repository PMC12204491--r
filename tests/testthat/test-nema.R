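flat_plate <- function(nx = 8, ny = 8) {
  # unit-spaced triangulated rectangle in the z = 0 plane
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i
  v <- as.matrix(expand.grid(x = 0:nx, y = 0:ny))
  v <- cbind(v, 0)
  tr <- NULL
  for (j in 1:ny) for (i in 1:nx) {
    a <- vid(i, j); b <- vid(i + 1L, j); c2 <- vid(i, j + 1L); d <- vid(i + 1L, j + 1L)
    tr <- rbind(tr, c(a, b, d), c(a, d, c2))
  }
  boundary <- which(v[, 1] %in% c(0, nx) | v[, 2] %in% c(0, ny))
  surface_mesh(v, tr, proximal = boundary, distal = integer())
}

test_that("element frames satisfy the metric identities", {
  fr <- element_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(fr$g1, c(1, 0, 0))
  expect_equal(fr$g2, c(0, 1, 0))
  expect_equal(fr$g, 1)
  expect_equal(fr$normal, c(0, 0, 1))
  expect_equal(fr$area, 0.5)

  # scaling by s scales the metric determinant by s^4
  set.seed(1)
  tri <- matrix(rnorm(9), 3)
  s <- 1.7
  expect_equal(element_frame(tri * s)$g, element_frame(tri)$g * s^4,
               tolerance = 1e-12)

  # rotation leaves the metric invariant
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_equal(element_frame(tri %*% R)$g, element_frame(tri)$g,
               tolerance = 1e-9)
  expect_error(element_frame(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "degenerate")
})

test_that("pressure converts from mmHg to N/cm^2", {
  expect_equal(pressure_to_stress_units(0), 0)
  expect_equal(pressure_to_stress_units(93.3), 1.2439, tolerance = 1e-4)
  expect_equal(pressure_to_stress_units(140), 1.8665, tolerance = 1e-4)
  expect_error(pressure_to_stress_units(-1), "non-negative")
})

test_that("zero pressure and zero stress are in equilibrium", {
  mesh <- make_cylinder_mesh(5, 10, 16, 4)
  pr <- membrane_problem(mesh, pressure = 0)
  r <- membrane_residual(pr, numeric(3 * nrow(mesh$vertices)))
  expect_equal(max(abs(r)), 0)
  expect_error(membrane_residual(pr, numeric(5)), "length")
})

test_that("a constant in-plane stress field is divergence-free on a plate", {
  mesh <- flat_plate(8, 8)
  pr <- membrane_problem(mesh, pressure = 0)
  nv <- nrow(mesh$vertices)
  # uniaxial tension along x in every node frame (e1 = x on a flat plate)
  dofs <- rep(c(1, 0, 0), nv)
  r <- membrane_residual(pr, dofs)
  scale <- max(abs(aaastress:::assemble_membrane_system(pr)$K))
  expect_lt(max(abs(r)) / scale, 1e-10)
})

test_that("the exact Laplace field drives the sphere residual to zero", {
  h <- 1.5; p_mmHg <- 93.3
  c0 <- pressure_to_stress_units(p_mmHg) * 25 / (2 * h)
  res_norm <- vapply(c(2, 3), function(sub) {
    band <- make_sphere_mesh(25, sub, band = 0.85)
    pr <- membrane_problem(band, thickness = h, pressure = p_mmHg)
    nv <- nrow(band$vertices)
    dofs <- rep(c(c0, c0, 0), nv) # isotropic tangent tension in any frame
    r <- membrane_residual(pr, dofs)
    sys <- aaastress:::assemble_membrane_system(pr)
    sqrt(sum(r^2)) / sqrt(sum(sys$f[sys$free_rows]^2))
  }, 0)
  expect_lt(res_norm[1], 0.1)
  expect_lt(res_norm[2], res_norm[1]) # refinement shrinks the defect
})

test_that("zero pressure gives zero stress from the solver", {
  mesh <- make_cylinder_mesh(5, 10, 16, 4)
  fld <- solve_membrane_stress(membrane_problem(mesh, pressure = 0))
  expect_lt(max(abs(fld$sigma1)), 1e-10)
  expect_lt(max(abs(fld$sigma2)), 1e-10)
})

test_that("a solve requires two boundary rings when ends are fixed", {
  sphere <- make_sphere_mesh(10, 2) # closed, no boundary
  pr <- membrane_problem(sphere, fixed = 1:5)
  expect_error(solve_membrane_stress(pr), "boundary rings")
})

test_that("cylinder solve recovers the thin-walled hoop stress", {
  sc <- solved_cylinder()
  fld <- sc$field
  pref <- pressure_to_stress_units(93.3) * 10 / 1.5
  mid <- abs(fld$cz - 50) < 10
  expect_lt(max(abs(fld$sigma1[mid] / pref - 1)), 0.03)
  # the hoop direction dominates: sigma2 (axial) much smaller
  expect_lt(max(abs(fld$sigma2[mid])) / pref, 0.2)
  expect_true(all(fld$sigma1 >= fld$sigma2))
  expect_true(any(fld$boundary) && !all(fld$boundary))
})

test_that("stress fields are objective and scale linearly in p and 1/h", {
  sc <- solved_cylinder()
  mesh <- sc$mesh; f1 <- sc$field
  th <- 0.8; ax <- 0.3
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3)
  m2 <- mesh
  m2$vertices <- mesh$vertices %*% (Rz %*% Rx) +
    matrix(c(12, -7, 31), nrow(mesh$vertices), 3, byrow = TRUE)
  f2 <- solve_membrane_stress(membrane_problem(m2))
  rel <- max(abs(f2$sigma1 - f1$sigma1)) / max(abs(f1$sigma1))
  expect_lt(rel, 1e-6)

  f_p2 <- solve_membrane_stress(membrane_problem(mesh, pressure = 2 * 93.3))
  expect_equal(f_p2$sigma1, 2 * f1$sigma1, tolerance = 1e-9)
  expect_equal(biomech_params(f_p2), {
    b <- biomech_params(f1); b[] <- lapply(b, `*`, 2); b
  }, tolerance = 1e-9)
  f_h2 <- solve_membrane_stress(membrane_problem(mesh, thickness = 0.75))
  expect_equal(f_h2$sigma1, 2 * f1$sigma1, tolerance = 1e-9)
})

test_that("biomech parameters match hand arithmetic", {
  two <- tibble::tibble(sigma1 = c(1, 3), area = c(3, 1))
  b <- biomech_params(two)
  expect_equal(b$mean_stress, 2)
  expect_equal(b$saws, 1.5)
  expect_equal(b$peak_wall_stress, 3)

  unif <- tibble::tibble(sigma1 = rep(4.2, 10), area = runif(10, 1, 2))
  bu <- biomech_params(unif)
  expect_true(all(abs(unlist(bu) - 4.2) < 1e-12))

  # ordering invariants on a real field
  fld <- solved_cylinder()$field
  br <- biomech_params(fld)
  expect_gte(br$peak_wall_stress, br$p99)
  expect_gte(br$p99, br$p75)
  expect_gte(br$peak_wall_stress, br$mean_stress)
  expect_gte(br$peak_wall_stress, br$saws)
  # area-weighted mode stays within the same bounds
  bw <- biomech_params(fld, area_weighted = TRUE)
  expect_gte(bw$peak_wall_stress, bw$p99)
  expect_equal(bw$saws, br$saws)
})

test_that("SAWS is stable under uniform mesh refinement", {
  # area-weighted average away from the flagged fixed-ring elements, where
  # the field is smooth
  saws <- vapply(c(64, 96), function(nc) {
    mesh <- make_cylinder_mesh(10, 60, nc, 24)
    fld <- solve_membrane_stress(membrane_problem(mesh))
    biomech_params(fld[!fld$boundary, ])$saws
  }, 0)
  expect_lt(abs(saws[2] - saws[1]) / saws[1], 0.01)
})

test_that("tidy and glance expose the per-element table and the summary", {
  fld <- solved_cylinder()$field
  td <- tidy(fld)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "stress_field"))
  expect_true(all(c("sigma1", "sigma2", "area", "boundary") %in% names(td)))
  g <- glance(fld)
  expect_lt(g$residual, 1e-8)
  expect_equal(g$n_elements, nrow(fld))
})

test_that("stress output files are written and re-readable", {
  fld <- solved_cylinder()$field
  fc <- tempfile(fileext = ".csv")
  fp <- tempfile(fileext = ".ply")
  fj <- tempfile(fileext = ".json")
  write_stress_csv(fld, fc)
  write_stress_ply(fld, fp)
  write_biomech_json(fld, fj)
  back <- utils::read.csv(fc)
  expect_equal(nrow(back), nrow(fld))
  m <- read_mesh_ply(fp)
  expect_equal(nrow(m$triangles), nrow(fld))
  b <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(b$saws, biomech_params(fld)$saws, tolerance = 1e-12)
})

test_that("ring distance is a breadth-first graph distance", {
  cyl <- make_cylinder_mesh(5, 10, 12, 5)
  rd <- mesh_ring_distance(cyl)
  expect_equal(sort(unique(rd)), 0:2) # 6 rings: 0,1,2 from nearer end
  expect_true(all(rd[cyl$proximal] == 0))
  expect_true(all(rd[cyl$distal] == 0))
})
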