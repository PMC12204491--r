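test_that("square mask contour has the expected area and orientation", {
  msk <- matrix(0L, 20, 20); msk[6:15, 5:14] <- 1L # 10 x 10 px
  ct <- mask_to_contours(msk, pixel_size = c(1, 1))
  expect_equal(length(unique(ct$contour_id)), 1L)
  a <- abs(sum(ct$x * ct$y[c(2:nrow(ct), 1)] - ct$x[c(2:nrow(ct), 1)] * ct$y) / 2)
  expect_lt(abs(a - 100), 5) # within one boundary ring of 10x10
  # counter-clockwise: positive signed area
  signed <- sum(ct$x * ct$y[c(2:nrow(ct), 1)] - ct$x[c(2:nrow(ct), 1)] * ct$y) / 2
  expect_gt(signed, 0)
})

test_that("sub-pixel extraction tracks a disk: perimeter within 2 percent", {
  dm <- disk_slice(64, 20)
  ct <- mask_to_contours(dm, pixel_size = c(1, 1))
  per <- sum(sqrt(diff(c(ct$x, ct$x[1]))^2 + diff(c(ct$y, ct$y[1]))^2))
  expect_lt(abs(per - 2 * pi * 20) / (2 * pi * 20), 0.02)
})

test_that("small components are filtered by min_area_px", {
  sp <- matrix(0L, 8, 8); sp[4, 4] <- 1L
  expect_equal(nrow(mask_to_contours(sp, min_area_px = 2, pixel_size = c(1, 1))), 0L)
  # an empty slice gives an empty table, not an error
  expect_equal(nrow(mask_to_contours(matrix(0L, 8, 8), pixel_size = c(1, 1))), 0L)
})

test_that("largest_only keeps the biggest component", {
  m <- matrix(0L, 40, 40)
  m[5:30, 5:30] <- 1L
  m[35:38, 35:38] <- 1L
  ct_all <- mask_to_contours(m, pixel_size = c(1, 1))
  ct_one <- mask_to_contours(m, pixel_size = c(1, 1), largest_only = TRUE)
  expect_equal(length(unique(ct_all$contour_id)), 2L)
  expect_equal(length(unique(ct_one$contour_id)), 1L)
})

test_that("contour_to_mask fills by pixel-centre point-in-polygon", {
  sq <- tibble::tibble(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  m <- contour_to_mask(sq, c(16, 16), c(1, 1))
  expect_equal(sum(m), 100)
  # brute-force oracle: count pixel centres inside the square
  centers_in <- sum(outer(seq_len(16) - 0.5, seq_len(16) - 0.5,
                          function(r, c2) r < 10 & c2 < 10))
  expect_equal(sum(m), centers_in)
  expect_error(contour_to_mask(tibble::tibble(x = c(0, 1), y = c(0, 1)),
                               c(8, 8), c(1, 1)), "at least")
  far <- tibble::tibble(x = c(0, 30, 30), y = c(0, 0, 30))
  expect_error(contour_to_mask(far, c(8, 8), c(1, 1)), "outside")
})

test_that("mask -> contour -> mask round trip keeps DSC >= 0.98", {
  for (r in c(8, 15, 22)) {
    dm <- disk_slice(64, r)
    ct <- mask_to_contours(dm, pixel_size = c(1, 1))
    m2 <- contour_to_mask(ct, c(64, 64), c(1, 1))
    expect_gte(dice_coefficient(m2, dm), 0.98)
  }
})

test_that("shoelace area of extracted contours matches pixel count", {
  set.seed(5)
  for (rep in 1:3) {
    r <- runif(1, 8, 20)
    dm <- disk_slice(64, r)
    ct <- mask_to_contours(dm, pixel_size = c(1, 1))
    n <- nrow(ct)
    a <- abs(sum(ct$x * ct$y[c(2:n, 1)] - ct$x[c(2:n, 1)] * ct$y) / 2)
    expect_lt(abs(a - sum(dm)), 2 * pi * r + 4) # one boundary ring
  }
})

test_that("resampling a circle to n = 4 gives the inscribed square", {
  ct <- circle_contour(r = 5, n = 256, cx = 10, cy = -3)
  r4 <- resample_contour(ct, 4)
  expect_equal(r4$x, c(15, 10, 5, 10), tolerance = 1e-9)
  expect_equal(r4$y, c(-3, 2, -3, -8), tolerance = 1e-9)
})

test_that("resampling preserves arc length within 0.5 percent for n >= 64", {
  ct <- circle_contour(r = 12, n = 200)
  per0 <- sum(sqrt(diff(c(ct$x, ct$x[1]))^2 + diff(c(ct$y, ct$y[1]))^2))
  for (n in c(64, 128)) {
    rn <- resample_contour(ct, n)
    pern <- sum(sqrt(diff(c(rn$x, rn$x[1]))^2 + diff(c(rn$y, rn$y[1]))^2))
    expect_lt(abs(pern - per0) / per0, 0.005)
  }
})

test_that("resampling equally spaced input to the same n is a rotation", {
  ct <- circle_contour(r = 7, n = 64)
  # rotate the starting point away from the +x convention
  ct2 <- ct[c(20:64, 1:19), ]
  rs <- resample_contour(ct2, 64)
  expect_equal(rs$x, ct$x, tolerance = 1e-9)
  expect_equal(rs$y, ct$y, tolerance = 1e-9)
  expect_error(resample_contour(ct, 2), "n >= 3")
})

test_that("hydraulic diameter: circle 2r, square a, ellipse by oracle", {
  expect_equal(hydraulic_diameter(circle_contour(r = 9, n = 256)), 18,
               tolerance = 1e-3)
  sq <- tibble::tibble(x = c(0, 3, 3, 0), y = c(0, 0, 3, 3))
  expect_equal(hydraulic_diameter(sq), 3)
  th <- 2 * pi * (0:4095) / 4096
  ell <- tibble::tibble(x = 3 * cos(th), y = 1 * sin(th))
  per <- sum(sqrt(diff(c(ell$x, ell$x[1]))^2 + diff(c(ell$y, ell$y[1]))^2))
  expect_equal(hydraulic_diameter(ell), 4 * (3 * pi) / per, tolerance = 1e-6)
  expect_error(hydraulic_diameter(tibble::tibble(x = c(0, 1, 2), y = c(0, 1, 2))),
               "degenerate")
})

test_that("diameter profile finds the bulge of a fusiform phantom", {
  ph <- small_phantom()
  ct <- mask_to_contours(ph$mask, largest_only = TRUE)
  prof <- diameter_profile(ct)
  expect_true(all(prof$d_h > 0))
  md <- max_hydraulic_diameter(ct)
  expect_lt(abs(md$d_max - 2 * ph$truth$r_max), ph$mask$pixel_size[1])
  expect_equal(md$slice_index, ph$truth$slice_max)
})

test_that("constant-radius stack gives a flat diameter profile", {
  ct <- dplyr::bind_rows(lapply(1:5, function(k) {
    dplyr::mutate(circle_contour(r = 10, n = 128), slice_index = k, z = k - 1)
  }))
  prof <- diameter_profile(ct)
  expect_lt(diff(range(prof$d_h)), 1e-9)
  one <- max_hydraulic_diameter(circle_contour(r = 10, n = 128))
  expect_equal(one$slice_index, 1L)
  expect_error(diameter_profile(circle_contour()[0, ]), "no contours")
})

test_that("contour tables round-trip through CSV and JSON", {
  ph <- small_phantom()
  ct <- mask_to_contours(ph$mask, largest_only = TRUE)
  ct <- ct[ct$slice_index <= 3, ]
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_contours_csv(ct, fc)
  write_contours_json(ct, fj)
  expect_equal(as.data.frame(read_contours_csv(fc)), as.data.frame(ct),
               tolerance = 1e-8)
  ctj <- read_contours_json(fj)
  expect_equal(ctj$x, ct$x, tolerance = 1e-12)
  expect_equal(ctj$slice_index, ct$slice_index)
})
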