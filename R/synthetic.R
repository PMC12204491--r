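#' Icosphere mesh, optionally cut to an equatorial band
#'
#' Subdivided icosahedron projected to radius `R`; `subdivisions = s` gives
#' `20 * 4^s` faces on the closed sphere. With `band` set, faces whose
#' vertices all satisfy `|z| <= band * R` are kept, leaving an open band with
#' two boundary loops near the poles (tagged proximal for `z > 0`) — the
#' validation geometry for the membrane solver, whose exact solution is the
#' Laplace law `sigma = p R / (2 h)`.
#'
#' @param R radius in mm.
#' @param subdivisions subdivision level (>= 0).
#' @param band `NULL` for the closed sphere, or a fraction in (0, 1): keep
#'   faces with all vertex `|z| <= band * R`.
#' @return a [surface_mesh()] with outward normals.
#' @export
make_sphere_mesh <- function(R, subdivisions = 3, band = NULL) {
  if (R <= 0) abort("R must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      idx <- nrow(v)
      assign(key, idx, envir = mid_cache)
      idx
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v * R
  # enforce outward winding per face
  cr <- {
    a <- v[f[, 2], ] - v[f[, 1], ]
    b <- v[f[, 3], ] - v[f[, 1], ]
    cbind(
      a[, 2] * b[, 3] - a[, 3] * b[, 2],
      a[, 3] * b[, 1] - a[, 1] * b[, 3],
      a[, 1] * b[, 2] - a[, 2] * b[, 1]
    )
  }
  centroid <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  inward <- rowSums(cr * centroid) < 0
  f[inward, ] <- f[inward, c(1, 3, 2)]
  if (is.null(band)) return(surface_mesh(v, f))
  if (band <= 0 || band >= 1) abort("band must be a fraction in (0, 1)")
  zmax <- band * R
  keep <- abs(v[f[, 1], 3]) <= zmax & abs(v[f[, 2], 3]) <= zmax &
    abs(v[f[, 3], 3]) <= zmax
  f <- f[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  mesh0 <- surface_mesh(v[used, , drop = FALSE], matrix(remap[f], ncol = 3))
  loops <- mesh_boundary_loops(mesh0)
  if (length(loops) != 2) abort("band cut did not produce two boundary loops")
  zm <- vapply(loops, function(l) mean(mesh0$vertices[l, 3]), 0)
  surface_mesh(
    mesh0$vertices, mesh0$triangles,
    proximal = loops[[which.max(zm)]], distal = loops[[which.min(zm)]]
  )
}

#' Open cylinder tube mesh with tagged end rings
#'
#' `n_circ * (n_len + 1)` vertices on rings `z = 0 ... L`; the thin-cylinder
#' membrane solution is hoop stress `p R / h` away from the fixed ends.
#'
#' @param R radius (mm), `L` length (mm).
#' @param L cylinder length in mm.
#' @param n_circ circumferential vertex count.
#' @param n_len number of axial segments.
#' @return a [surface_mesh()] (proximal ring at `z = 0`).
#' @export
make_cylinder_mesh <- function(R, L, n_circ = 64, n_len = 32) {
  if (R <= 0 || L <= 0 || n_circ < 8 || n_len < 1) {
    abort("invalid cylinder parameters")
  }
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  contours <- purrr::map_dfr(0:n_len, function(k) {
    tibble(
      slice_index = k + 1L, z = L * k / n_len, contour_id = 1L,
      x = R * cos(theta), y = R * sin(theta)
    )
  })
  loft_contours(contours, n_circ = n_circ)
}

#' Fusiform AAA phantom specification
#'
#' An analytically known stand-in for a clinical CTA: a tube with a Gaussian
#' bulge, radius profile `r(z) = R0 + dR * exp(-(z - z0)^2 / (2 s^2))`,
#' optionally with a sinusoidally offset centerline (tortuosity). The
#' voxelized mask, a CTA-like noisy image (foreground/background intensities
#' plus Gaussian noise and optional bright streak "metal artifacts"), and the
#' analytic ground truth are generated together, so every derived quantity
#' (max diameter, areas, stress trends) can be checked in closed form.
#'
#' Defaults emulate a moderate aneurysm at CT resolution: baseline radius
#' 11 mm bulging to 22 mm (44 mm maximum diameter), 96 mm of axis, 0.85 mm
#' pixels, 3 mm slices.
#'
#' @param R0 baseline (neck) radius, mm.
#' @param dR bulge amplitude, mm.
#' @param z0 bulge centre along the axis, mm (default mid-length).
#' @param s bulge Gaussian width, mm.
#' @param L axial length, mm.
#' @param offset centerline offset amplitude, mm (0 = straight).
#' @param pixel_size in-plane mm/px (length 2 or scalar).
#' @param slice_spacing mm between slices.
#' @param noise_sd additive Gaussian intensity noise sd.
#' @param n_artifacts number of bright streak artifacts.
#' @param fg,bg foreground / background image intensities.
#' @param margin_px in-plane margin between vessel and grid edge, px.
#' @param seed RNG seed for noise and artifacts.
#' @return a `fusiform_spec` list.
#' @export
fusiform_spec <- function(R0 = 11, dR = 11, z0 = NULL, s = 16, L = 96,
                          offset = 0, pixel_size = 0.85, slice_spacing = 3,
                          noise_sd = 10, n_artifacts = 0, fg = 150, bg = 30,
                          margin_px = 6, seed = 1L) {
  if (R0 <= 0 || L <= 0 || s <= 0 || dR < 0 || margin_px < 0) {
    abort("invalid fusiform geometry")
  }
  if (is.null(z0)) z0 <- L / 2
  structure(
    list(
      R0 = R0, dR = dR, z0 = z0, s = s, L = L, offset = offset,
      pixel_size = rep_len(as.numeric(pixel_size), 2L),
      slice_spacing = slice_spacing, noise_sd = noise_sd,
      n_artifacts = as.integer(n_artifacts), fg = fg, bg = bg,
      margin_px = as.integer(margin_px), seed = as.integer(seed)
    ),
    class = "fusiform_spec"
  )
}

fusiform_radius <- function(spec, z) {
  spec$R0 + spec$dR * exp(-(z - spec$z0)^2 / (2 * spec$s^2))
}

fusiform_center <- function(spec, z) {
  c(spec$offset * sin(pi * z / spec$L), 0)
}

#' Generate a fusiform AAA phantom volume
#'
#' @param spec a [fusiform_spec()].
#' @return list with `image` (3D numeric array, slice/row/col), `mask`
#'   (ground-truth [mask_volume()]), and `truth` (analytic record: `r_max`,
#'   `z_max`, the radius function, grid geometry).
#' @export
make_fusiform_phantom <- function(spec) {
  stopifnot(inherits(spec, "fusiform_spec"))
  dx <- spec$pixel_size[1]; dy <- spec$pixel_size[2]
  r_peak <- spec$R0 + spec$dR
  half_extent <- r_peak + abs(spec$offset) + spec$margin_px * max(dx, dy)
  npx <- 2L * ceiling(half_extent / dx)
  npy <- 2L * ceiling(half_extent / dy)
  ns <- floor(spec$L / spec$slice_spacing) + 1L
  cx0 <- npx * dx / 2; cy0 <- npy * dy / 2
  if (half_extent > cx0 || half_extent > cy0) abort("radius exceeds grid")
  px <- ((seq_len(npx)) - 0.5) * dx
  py <- ((seq_len(npy)) - 0.5) * dy
  vox <- array(0L, c(ns, npy, npx))
  zs <- (seq_len(ns) - 1L) * spec$slice_spacing
  for (k in seq_len(ns)) {
    r <- fusiform_radius(spec, zs[k])
    ctr <- fusiform_center(spec, zs[k])
    d2 <- outer((py - (cy0 + ctr[2]))^2, (px - (cx0 + ctr[1]))^2, `+`)
    vox[k, , ] <- (d2 <= r^2) * 1L
  }
  mask <- mask_volume(vox, spec$pixel_size, spec$slice_spacing)
  set.seed(spec$seed)
  img <- array(spec$bg, dim(vox))
  img[vox == 1L] <- spec$fg
  if (spec$n_artifacts > 0) {
    for (k in seq_len(ns)) {
      img[k, , ] <- add_streak_artifacts(img[k, , ], spec$n_artifacts,
                                         intensity = 3 * spec$fg)
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + array(rnorm(length(img), sd = spec$noise_sd), dim(img))
  }
  izmax <- which.max(fusiform_radius(spec, zs))
  list(
    image = img, mask = mask,
    truth = list(
      r_max = max(fusiform_radius(spec, zs)), z_max = zs[izmax],
      slice_max = izmax, radius = function(z) fusiform_radius(spec, z),
      center = function(z) fusiform_center(spec, z),
      grid_center = c(cx0, cy0), spec = spec
    )
  )
}

# bright blurred line segments crossing the slice (spinal-screw-like streaks)
add_streak_artifacts <- function(slice, n, intensity) {
  nr <- nrow(slice); nc <- ncol(slice)
  for (i in seq_len(n)) {
    theta <- runif(1, 0, pi)
    offs <- runif(1, -0.25, 0.25) * min(nr, nc)
    rr <- row(slice) - nr / 2
    cc <- col(slice) - nc / 2
    d <- abs(rr * cos(theta) + cc * sin(theta) - offs)
    slice <- slice + intensity * exp(-d^2 / (2 * 1.2^2))
  }
  slice
}

#' Patch training set from random fusiform phantoms
#'
#' Draws phantoms with randomized geometry inside physiological ranges and
#' cuts `n` image/mask patch pairs, roughly half containing a piece of the
#' wall boundary and half not (background or deep interior), the class
#' balance a patch-based segmentation model needs. Images are rescaled to
#' `[0, 1]`.
#'
#' @param n number of patch pairs.
#' @param patch_size patch edge in px (default 64).
#' @param seed RNG seed; the whole set is reproducible from it.
#' @param n_phantoms number of distinct phantoms to draw from.
#' @param noise_sd,n_artifacts forwarded to [fusiform_spec()].
#' @return list with arrays `x` and `y` of dim `(patch, patch, n)` and the
#'   tibble `info` (source phantom, offsets, boundary flag).
#' @export
phantom_dataset <- function(n, patch_size = 64, seed = 1L, n_phantoms = 8,
                            noise_sd = 10, n_artifacts = 0) {
  if (n < 1) abort("need n >= 1")
  set.seed(seed)
  specs <- purrr::map(seq_len(n_phantoms), function(i) {
    fusiform_spec(
      R0 = runif(1, 9, 13), dR = runif(1, 6, 14), s = runif(1, 12, 20),
      L = 96, offset = runif(1, 0, 4),
      pixel_size = 0.85, slice_spacing = 3,
      noise_sd = noise_sd, n_artifacts = n_artifacts,
      margin_px = 44, # wide field of view so vessel-free patches exist
      seed = sample.int(1e6, 1)
    )
  })
  phantoms <- purrr::map(specs, make_fusiform_phantom)
  imax <- max(purrr::map_dbl(phantoms, ~ max(.x$image)))
  x <- array(0, c(patch_size, patch_size, n))
  y <- array(0, c(patch_size, patch_size, n))
  info <- vector("list", n)
  for (i in seq_len(n)) {
    want_boundary <- i %% 2L == 0L
    tries <- 0L
    repeat {
      tries <- tries + 1L
      ph <- phantoms[[sample.int(n_phantoms, 1)]]
      d <- dim(ph$image)
      k <- sample.int(d[1], 1)
      if (d[2] < patch_size || d[3] < patch_size) {
        abort("phantom slices smaller than patch_size")
      }
      r0 <- sample.int(d[2] - patch_size + 1L, 1)
      c0 <- sample.int(d[3] - patch_size + 1L, 1)
      mpatch <- ph$mask$voxels[k, r0:(r0 + patch_size - 1L),
                               c0:(c0 + patch_size - 1L)]
      frac <- mean(mpatch)
      has_boundary <- frac > 0.02 && frac < 0.98
      if (has_boundary == want_boundary || tries > 200L) {
        x[, , i] <- pmin(pmax(
          ph$image[k, r0:(r0 + patch_size - 1L),
                   c0:(c0 + patch_size - 1L)] / imax, 0), 1)
        y[, , i] <- mpatch
        info[[i]] <- tibble(
          patch = i, slice = k, row0 = r0, col0 = c0, boundary = has_boundary
        )
        break
      }
    }
  }
  list(x = x, y = y, info = dplyr::bind_rows(info))
}
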