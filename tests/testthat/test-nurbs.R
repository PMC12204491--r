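test_that("clamped uniform knot vectors match the closed forms", {
  expect_equal(nurbs_knots(4, 3), c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(nurbs_knots(5, 2), c(0, 0, 0, 1 / 3, 2 / 3, 1, 1, 1))
  expect_equal(nurbs_knots(2, 1), c(0, 0, 1, 1))
  expect_error(nurbs_knots(3, 3), "degree")
})

test_that("degree-0 basis is the knot-span indicator", {
  U <- c(0, 0.25, 0.5, 1)
  expect_equal(bspline_basis(0, 0, c(0.1, 0.3, 0.7), U), c(1, 0, 0))
  expect_equal(bspline_basis(1, 0, c(0.1, 0.3, 0.7), U), c(0, 1, 0))
  expect_equal(bspline_basis(2, 0, c(0.1, 0.3, 1.0), U), c(0, 0, 1))
})

test_that("basis functions are a partition of unity and match Bernstein", {
  # Bezier case p=2: Bernstein polynomials at t=0.5
  expect_equal(
    as.numeric(bspline_basis_matrix(0.5, 2, c(0, 0, 0, 1, 1, 1))),
    c(0.25, 0.5, 0.25)
  )
  set.seed(1)
  for (p in 1:3) {
    U <- nurbs_knots(p + 4, p)
    N <- bspline_basis_matrix(runif(40), p, U)
    expect_equal(rowSums(N), rep(1, 40), tolerance = 1e-12)
  }
})

test_that("rational partition of unity holds to 1e-12 for random curves", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(5:12, 1); p <- sample(1:3, 1)
    w <- runif(n, 0.2, 3)
    U <- nurbs_knots(n, p)
    tt <- runif(30)
    N <- bspline_basis_matrix(tt, p, U)
    Nw <- sweep(N, 2, w, `*`)
    expect_equal(rowSums(Nw / rowSums(Nw)), rep(1, 30), tolerance = 1e-12)
  }
})

test_that("unit weights reduce evaluation to the non-rational B-spline", {
  set.seed(3)
  cp <- cbind(cumsum(runif(8)), cumsum(rnorm(8)))
  cv <- nurbs_curve(cp, weights = 1, degree = 3)
  tt <- seq(0, 1, length.out = 33)
  N <- bspline_basis_matrix(tt, 3, cv$knots)
  expect_equal(nurbs_evaluate(cv, tt), N %*% cp, tolerance = 1e-13)
  # clamped endpoint interpolation
  expect_equal(nurbs_evaluate(cv, 0)[1, ], cp[1, ], tolerance = 1e-13)
  expect_equal(nurbs_evaluate(cv, 1)[1, ], cp[8, ], tolerance = 1e-13)
})

test_that("degree-1 curve linearly interpolates control points", {
  cv <- nurbs_curve(rbind(c(0, 0), c(2, 0)), degree = 1)
  expect_equal(nurbs_evaluate(cv, 0.5)[1, ], c(1, 0))
})

test_that("the 9-point rational quadratic circle is exact to 1e-9", {
  w <- sqrt(2) / 2
  cp <- rbind(
    c(1, 0), c(1, 1), c(0, 1), c(-1, 1), c(-1, 0),
    c(-1, -1), c(0, -1), c(1, -1), c(1, 0)
  )
  kn <- c(0, 0, 0, 0.25, 0.25, 0.5, 0.5, 0.75, 0.75, 1, 1, 1)
  circ <- nurbs_curve(cp, weights = c(1, w, 1, w, 1, w, 1, w, 1),
                      degree = 2, knots = kn)
  pts <- nurbs_evaluate(circ, seq(0, 1, length.out = 2001))
  expect_lt(max(abs(sqrt(rowSums(pts^2)) - 1)), 1e-9)
})

test_that("fitting recovers a curve its data were sampled from", {
  set.seed(4)
  cp <- cbind(5 * cos(2 * pi * (0:9) / 10), 5 * sin(2 * pi * (0:9) / 10))
  cp <- rbind(cp, cp[1, ]) # seam-closed generator
  gen <- nurbs_curve(cp, degree = 3)
  tt <- seq(0, 1, length.out = 400)
  pts <- nurbs_evaluate(gen, tt)
  # data sampled at known parameters: supplying them makes the fit exact
  fit <- nurbs_fit(
    tibble::tibble(x = pts[-400, 1], y = pts[-400, 2]),
    n_ctrl = 11, degree = 3, params = tt
  )
  expect_lt(attr(fit, "max_fit_residual"), 1e-6)
})

test_that("a cubic 16-control-point fit tracks a 10 mm circle to 0.05 mm", {
  ct <- circle_contour(r = 10, n = 200)
  fit <- nurbs_fit(ct, n_ctrl = 16, degree = 3)
  samp <- nurbs_evaluate(fit, seq(0, 1, length.out = 2001))
  expect_lt(max(abs(sqrt(rowSums(samp^2)) - 10)), 0.05)
  expect_error(nurbs_fit(circle_contour(n = 10), n_ctrl = 12), "underdetermined")
  g <- glance(fit)
  expect_equal(g$n_ctrl, 16L)
  expect_lt(g$max_fit_residual, 0.05)
})

test_that("edits are pure, local, and weight changes pull the curve", {
  set.seed(5)
  cp <- cbind(cumsum(runif(12, 0.5, 1)), cumsum(rnorm(12)))
  cv <- nurbs_curve(cp, degree = 3)
  expect_equal(nurbs_edit(cv, tibble::tibble(index = integer(), dx = numeric(),
                                             dy = numeric())), cv)
  ed <- nurbs_edit(cv, tibble::tibble(index = 2, dx = 1.5, dy = -1))
  # unedited control points bitwise unchanged
  expect_identical(ed$control_points[-2, ], cv$control_points[-2, ])
  # local support: parameters beyond the p+1 affected spans are untouched
  tt_far <- seq(0.75, 1, length.out = 50)
  expect_equal(nurbs_evaluate(ed, tt_far), nurbs_evaluate(cv, tt_far),
               tolerance = 1e-12)
  expect_error(nurbs_edit(cv, tibble::tibble(index = 99, dx = 0, dy = 0)),
               "out of range")

  # doubling a weight pulls the curve toward that control point
  mid_span <- function(curve, i) {
    U <- curve$knots; p <- curve$degree
    (U[i + 1] + U[i + p + 1]) / 2 # middle of N_i's support
  }
  t0 <- mid_span(cv, 6)
  d_before <- sqrt(sum((nurbs_evaluate(cv, t0) - cp[6, ])^2))
  up <- nurbs_edit(cv, tibble::tibble(index = 6, dx = 0, dy = 0, new_weight = 2))
  d_after <- sqrt(sum((nurbs_evaluate(up, t0) - cp[6, ])^2))
  expect_lt(d_after, d_before)
})

test_that("curves are affine equivariant and stay in the convex hull", {
  set.seed(6)
  cp <- cbind(runif(9), runif(9))
  cv <- nurbs_curve(cp, degree = 3)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(3, -2)
  cv_t <- nurbs_curve(sweep(cp %*% R, 2, shift, `+`), degree = 3)
  tt <- seq(0, 1, length.out = 41)
  expect_equal(nurbs_evaluate(cv_t, tt),
               sweep(nurbs_evaluate(cv, tt) %*% R, 2, shift, `+`),
               tolerance = 1e-12)
  # convex hull via chull: every curve point inside the control polygon hull
  hull <- grDevices::chull(cp)
  poly <- cp[hull, , drop = FALSE]
  pts <- nurbs_evaluate(cv, tt)
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), pts)
  on_edge <- vapply(seq_len(nrow(pts)), function(i) {
    min(sqrt(rowSums(sweep(poly, 2, pts[i, ])^2))) < 1e-8
  }, logical(1))
  expect_true(all(inside | on_edge))
})

test_that("sampling a fitted curve preserves area and rasterizes back", {
  dm <- disk_slice(64, 20)
  ct <- mask_to_contours(dm, pixel_size = c(1, 1))
  fit <- nurbs_fit(ct)
  rc <- nurbs_to_contour(fit, 256)
  n <- nrow(rc)
  a_fit <- abs(sum(rc$x * rc$y[c(2:n, 1)] - rc$x[c(2:n, 1)] * rc$y) / 2)
  n0 <- nrow(ct)
  a_src <- abs(sum(ct$x * ct$y[c(2:n0, 1)] - ct$x[c(2:n0, 1)] * ct$y) / 2)
  expect_lt(abs(a_fit - a_src) / a_src, 0.01)
  m2 <- contour_to_mask(rc, c(64, 64), c(1, 1))
  expect_gte(dice_coefficient(m2, dm), 0.98)

  # degree-1 curve is the control polygon
  cp <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(0, 0))
  poly <- nurbs_curve(cp, degree = 1)
  samp <- nurbs_evaluate(poly, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(samp, cp, tolerance = 1e-12)
})

test_that("curves serialize to JSON and back", {
  cv <- nurbs_fit(circle_contour(r = 8, n = 64), n_ctrl = 10)
  f <- tempfile(fileext = ".json")
  write_nurbs_json(cv, f)
  cv2 <- read_nurbs_json(f)
  expect_equal(cv2$control_points, cv$control_points, tolerance = 1e-12)
  expect_equal(cv2$knots, cv$knots)
  expect_equal(cv2$degree, cv$degree)
})
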