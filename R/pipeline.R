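#' Pipeline configuration
#'
#' One object drives the whole mask-to-stress pipeline. Defaults reflect the
#' standard AAA analysis conditions: uniform 1.5 mm wall thickness and a mean
#' arterial pressure of 93.3 mmHg with fixed proximal and distal ends.
#'
#' @param input path to a mask volume (`.nii`/`.nii.gz` or a PNG-stack
#'   directory), or a [mask_volume()] object directly.
#' @param output_dir directory for all stage outputs.
#' @param pixel_size,slice_spacing spacing overrides (mm); `NULL` keeps the
#'   input metadata.
#' @param refine apply NURBS refinement to every slice contour.
#' @param edits_file optional JSON file of control-point edits, a list of
#'   `{slice_index, index, dx, dy, new_weight}` records.
#' @param n_ctrl,degree NURBS fit settings (see [nurbs_fit()]).
#' @param smooth_contours fit-and-resample every contour with a NURBS curve
#'   before lofting (default `TRUE`). Voxel-scale wiggle in iso-contours
#'   perturbs the local surface curvature that membrane equilibrium divides
#'   by, biasing the stress field; the smoothing pass restores the
#'   curvature fidelity of the underlying anatomy. Diameters are always
#'   measured on the raw mask contours.
#' @param n_circ circumferential mesh resolution.
#' @param min_area_px contour area filter (px).
#' @param thickness_mm wall thickness `h` (mm).
#' @param pressure_mmHg intraluminal pressure (mmHg).
#' @param seed seed recorded in the manifest (the solve itself is
#'   deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir, pixel_size = NULL,
                            slice_spacing = NULL, refine = FALSE,
                            edits_file = NULL, n_ctrl = NULL, degree = 3,
                            smooth_contours = TRUE, n_circ = 64,
                            min_area_px = 2, thickness_mm = 1.5,
                            pressure_mmHg = 93.3, seed = 1L) {
  structure(
    list(
      input = input, output_dir = output_dir, pixel_size = pixel_size,
      slice_spacing = slice_spacing, refine = refine,
      edits_file = edits_file, n_ctrl = n_ctrl, degree = degree,
      smooth_contours = smooth_contours,
      n_circ = n_circ, min_area_px = min_area_px,
      thickness_mm = thickness_mm, pressure_mmHg = pressure_mmHg,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> h = %g mm, p = %g mmHg, n_circ = %d, refine = %s\n",
    x$thickness_mm, x$pressure_mmHg, x$n_circ, x$refine
  ))
  invisible(x)
}

load_pipeline_input <- function(config) {
  inp <- config$input
  mask <- if (is_mask_volume(inp)) {
    inp
  } else if (dir.exists(inp)) {
    read_mask_slices(inp)
  } else {
    read_mask_nifti(inp)
  }
  if (!is.null(config$pixel_size)) {
    mask$pixel_size <- rep_len(as.numeric(config$pixel_size), 2L)
  }
  if (!is.null(config$slice_spacing)) {
    mask$slice_spacing <- as.numeric(config$slice_spacing)
  }
  mask
}

pipeline_stage <- function(report, stage, expr, output_dir) {
  tryCatch(expr, error = function(e) {
    writeLines(
      c(sprintf("stage: %s", stage), conditionMessage(e)),
      file.path(output_dir, "FAILED")
    )
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full mask-to-stress pipeline
#'
#' Stages: load mask, extract per-slice contours (largest component),
#' optional NURBS fit/edit/resample, loft into an open-tube mesh, solve the
#' inverse membrane problem, and summarize. Writes contours (CSV), the mesh
#' (PLY), the stress field (CSV + PLY with per-face `sigma1`), the diameter
#' profile and biomechanical report (JSON/CSV), and a provenance manifest
#' (config hash, package version, seed). Identical config and input give
#' identical outputs; any stage failure aborts with a stage-labelled error
#' and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return an `aaa_report`: list with `biomech` (one-row tibble), `diameters`,
#'   `max_diameter`, `field`, `mesh`, `paths`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))

  mask <- pipeline_stage(NULL, "load", load_pipeline_input(config), out)
  contours <- pipeline_stage(NULL, "contours", {
    ct <- mask_to_contours(mask, min_area_px = config$min_area_px,
                           largest_only = TRUE)
    if (nrow(ct) == 0L) abort("no contours found in mask")
    ct
  }, out)

  if (isTRUE(config$refine)) {
    contours <- pipeline_stage(NULL, "refine", {
      edits <- if (!is.null(config$edits_file)) {
        jsonlite::read_json(config$edits_file, simplifyVector = TRUE)
      } else {
        NULL
      }
      # only slices addressed by an edit are re-fit; with no edits the
      # refinement stage is a bit-exact no-op (the "revert to automatic
      # segmentation" workflow)
      refine_contours(contours, edits = edits, n_ctrl = config$n_ctrl,
                      degree = config$degree, edited_slices_only = TRUE)
    }, out)
  }

  mesh <- pipeline_stage(NULL, "mesh", {
    mesh_contours <- if (isTRUE(config$smooth_contours)) {
      refine_contours(contours, n_ctrl = config$n_ctrl, degree = config$degree)
    } else {
      contours
    }
    loft_contours(mesh_contours, n_circ = config$n_circ)
  }, out)
  field <- pipeline_stage(NULL, "stress", {
    problem <- membrane_problem(mesh, thickness = config$thickness_mm,
                                pressure = config$pressure_mmHg)
    solve_membrane_stress(problem)
  }, out)

  diam <- diameter_profile(contours)
  maxd <- max_hydraulic_diameter(contours)
  biomech <- biomech_params(field)

  paths <- list(
    contours = file.path(out, "contours.csv"),
    mesh = file.path(out, "mesh.ply"),
    stress_csv = file.path(out, "stress.csv"),
    stress_ply = file.path(out, "stress.ply"),
    diameters = file.path(out, "diameters.csv"),
    biomech = file.path(out, "biomech.json"),
    manifest = file.path(out, "manifest.json")
  )
  write_contours_csv(contours, paths$contours)
  write_mesh_ply(mesh, paths$mesh)
  write_stress_csv(field, paths$stress_csv)
  write_stress_ply(field, paths$stress_ply)
  utils::write.csv(diam, paths$diameters, row.names = FALSE)
  write_biomech_json(field, paths$biomech)

  cfg_for_hash <- config
  cfg_for_hash$input <- if (is_mask_volume(config$input)) "<in-memory mask>" else config$input
  manifest <- list(
    package = "aaastress",
    version = as.character(utils::packageVersion("aaastress")),
    config = cfg_for_hash[setdiff(names(cfg_for_hash), "input")],
    input = cfg_for_hash$input,
    config_hash = rlang::hash(cfg_for_hash),
    seed = config$seed,
    n_slices = dim(mask$voxels)[1],
    n_elements = nrow(field),
    residual = attr(field, "residual")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  structure(
    list(
      biomech = biomech, diameters = diam, max_diameter = maxd,
      field = field, mesh = mesh, contours = contours,
      paths = paths, manifest = manifest
    ),
    class = "aaa_report"
  )
}

#' @export
print.aaa_report <- function(x, ...) {
  cat("<aaa_report>\n")
  cat(sprintf("  max hydraulic diameter: %.2f mm (slice %d)\n",
              x$max_diameter$d_max, x$max_diameter$slice_index))
  b <- x$biomech
  cat(sprintf(
    "  wall stress (N/cm^2): PWS %.3f | p99 %.3f | p75 %.3f | mean %.3f | SAWS %.3f\n",
    b$peak_wall_stress, b$p99, b$p75, b$mean_stress, b$saws
  ))
  invisible(x)
}

#' NURBS-refine every slice contour of a stack
#'
#' Fits a curve per slice, applies any edits addressed to that slice, and
#' resamples back to a contour. With no edits this is a smoothing pass
#' (and with dense control points an identity to within fit residual).
#'
#' @param contours contour tibble (one contour per slice).
#' @param edits `NULL`, or a data frame with columns `slice_index`, `index`,
#'   `dx`, `dy` and optional `new_weight`.
#' @param n_ctrl,degree see [nurbs_fit()].
#' @param n_samples points per refined contour (default: the per-slice input
#'   count).
#' @param edited_slices_only pass slices without edits through untouched
#'   (bit-exact); `FALSE` re-fits every slice, making this a smoothing pass.
#' @return a contour tibble.
#' @export
refine_contours <- function(contours, edits = NULL, n_ctrl = NULL, degree = 3,
                            n_samples = NULL, edited_slices_only = FALSE) {
  purrr::map_dfr(split(contours, contours$slice_index), function(piece) {
    my <- if (!is.null(edits) && nrow(edits) > 0) {
      edits[edits$slice_index == piece$slice_index[1], , drop = FALSE]
    } else {
      NULL
    }
    if (isTRUE(edited_slices_only) && (is.null(my) || nrow(my) == 0)) {
      return(piece)
    }
    curve <- nurbs_fit(piece, n_ctrl = n_ctrl, degree = degree)
    if (!is.null(my) && nrow(my) > 0) curve <- nurbs_edit(curve, my)
    ns <- n_samples %||% nrow(piece)
    nurbs_to_contour(curve, max(8L, ns), slice_index = piece$slice_index[1],
                     z = piece$z[1])
  })
}

#' Compare two biomechanical reports over a geometry set
#'
#' For paired runs over the same geometries (e.g. ground-truth masks vs
#' predicted masks), gives per-parameter mean difference, mean absolute
#' difference, and the coefficient of determination R^2 (squared Pearson
#' correlation) across the set.
#'
#' @param a,b lists of `aaa_report` objects (or data frames of
#'   [biomech_params()] rows plus `d_max`), same length and order.
#' @return tibble with one row per parameter.
#' @export
compare_reports <- function(a, b) {
  to_df <- function(r) {
    if (is.data.frame(r)) return(as_tibble(r))
    purrr::map_dfr(r, function(x) {
      dplyr::bind_cols(x$biomech, tibble(d_max = x$max_diameter$d_max))
    })
  }
  da <- to_df(a); db <- to_df(b)
  if (nrow(da) != nrow(db)) abort("report sets have different lengths")
  params <- intersect(names(da), names(db))
  purrr::map_dfr(params, function(p) {
    va <- da[[p]]; vb <- db[[p]]
    tibble(
      parameter = p,
      mean_diff = mean(vb - va),
      mean_abs_diff = mean(abs(vb - va)),
      r_squared = if (nrow(da) > 1 && sd(va) > 0 && sd(vb) > 0) {
        cor(va, vb)^2
      } else if (all(va == vb)) 1 else NA_real_
    )
  })
}

#' Plot a diameter profile
#'
#' @param profile tibble from [diameter_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_diameter_profile <- function(profile, ...) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$z, .data$d_h)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "z (mm)", y = "hydraulic diameter (mm)")
}
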