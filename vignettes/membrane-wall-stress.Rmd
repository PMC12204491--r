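---
title: "Inverse membrane wall stress for AAA: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse membrane wall stress for AAA: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: what is modelled,
which knobs matter, where the design was genuinely open and what we chose,
and what passing the test suite does and does not establish.

## The membrane model and its assumptions

An abdominal aortic aneurysm imaged by CTA is seen in its deformed, loaded
configuration, under (approximately) mean arterial pressure. For a thin
pressurized shell whose bending stiffness is negligible, the wall is
*statically determinate*: internal force balance alone fixes the stress,
with no constitutive law. On a parameterized surface with covariant tangent
vectors $g_\alpha$, metric determinant $g$, thickness $h$, pressure $p$ and
outward unit normal $n$, equilibrium reads

$$\frac{1}{\sqrt g}\left(\sqrt g\, h\, \sigma^{\alpha\beta} g_\alpha\right)_{,\beta} + p\,n = 0,$$

with the Cauchy components $\sigma^{\alpha\beta}$ ($\alpha,\beta\in\{1,2\}$)
as the only unknowns. The assumptions bought with this economy:

- **Membrane state.** No bending moments, no transmural stress gradient. Near
  clamped boundaries and sharp geometric kinks a real wall carries bending;
  the model does not.
- **Deformed-configuration input.** The mesh is already the pressurized
  shape; we never need (and never compute) an unloaded reference
  configuration.
- **Uniform thickness and pressure.** Defaults $h = 1.5$ mm and
  $p = 93.3$ mmHg (mean arterial pressure) — the standard AAA analysis
  conditions; both are scalar parameters of `membrane_problem()`.
- **Single conduit.** One outer-wall tube between a proximal and a distal
  ring; no bifurcation, no intraluminal thrombus, no lumen surface.

Units: geometry in mm, pressure input in mmHg, all reported stresses in
N/cm² (1 mmHg = 133.322 Pa = 1.33322e-2 N/cm², see
`pressure_to_stress_units()`).

## Discretization

Linear (P1) shape functions on the triangulated surface carry both the test
space and the stress interpolation. The stress unknowns live at the *nodes*:
three components of the symmetric in-plane stress tensor per vertex,
expressed in a per-vertex orthonormal tangent frame built from the
area-weighted vertex normal. Inside an element, nodal tensors are projected
into the element's contravariant basis, interpolated linearly, and tested
against each free node and each spatial direction, which yields a sparse
linear system $K s = f$ (the pressure load is the right-hand side). The
per-node frame is a necessity, not a flourish: raw contravariant components
cannot be shared across elements whose local bases differ.

Three deliberate numerical choices:

1. **Fixed ends by row deletion.** "Fixed proximal and distal rings" has no
   direct meaning in a stress-only unknown set; we drop the equilibrium rows
   of boundary nodes (their reaction forces are unknowns we do not solve
   for). Elements touching a fixed node are reported but flagged
   (`boundary` column), and summaries can exclude them.
2. **Regularized least squares.** Removing rows makes the system
   rectangular; it is solved via the normal equations with a Tikhonov ridge
   of `1e-10` times the diagonal scale, taken on the tensor *Frobenius*
   norm (the shear component counts twice). The Frobenius form matters:
   a plain ridge on the raw coefficient vector selects minimum-norm values
   for equilibrium-indifferent modes (e.g. the uniform axial stress of an
   open cylinder) in a frame-*dependent* way and breaks rigid-motion
   objectivity; the tensor norm restores exact equivariance.
3. **Checkerboard stabilization.** Equal-order nodal interpolation of all
   three stress components admits oscillatory near-null modes: states with
   essentially zero equilibrium residual but node-to-node alternation. We
   damp them with a smoothness penalty on the *difference of physical nodal
   stress tensors across each edge, after parallel transport* (the
   neighbour's tangent plane is rotated onto the node's by the minimal
   rotation between normals, Rodrigues form). The transported difference
   vanishes for covariantly constant fields — in particular the exact
   Laplace solutions on spheres and cylinders — so the penalty suppresses
   discretization artefacts without biasing smooth physics. Its weight
   (`smoothing`, default 0.1 relative to the normal-equation diagonal) is
   the one tunable numerical parameter; the test suite verifies that with
   it the sphere error converges monotonically under refinement and rigid
   motions change stresses by less than $10^{-6}$ relative.

The assembled system is linear in the stress for a fixed geometry; the
solver is written as a Newton iteration with the analytic Jacobian, which
therefore converges in one step (tolerance `1e-8` on the relative gradient
norm, cap of 100 iterations) while leaving room for nonlinear extensions.
Nodal solutions are evaluated at element centroids by shape-function
interpolation; the contravariant components are pushed to a local
orthonormal frame through the metric and eigendecomposed into physical
principal stresses $\sigma_1 \ge \sigma_2$.

From the $\sigma_1$ field, `biomech_params()` reports peak wall stress, the
99th and 75th percentiles, the mean, and SAWS. Only SAWS is area-weighted by
definition; the paper-standard convention for the other four is not fixed
anywhere we could find, so they are element-unweighted by default with an
`area_weighted = TRUE` mode. Percentiles use R's default (type 7, linear
interpolation) estimator.

## Geometry processing

**Contours.** Slices are iso-contoured at level 0.5 after a separable
[1 2 1]/4 pre-smoothing, marching-squares style (`grDevices::contourLines`),
one closed counter-clockwise polyline per component in physical mm. The
pre-smoothing is what makes perimeters honest: on a binary staircase the
0.5 level overestimates a disk's perimeter by about 6%, with smoothing the
error drops below 2%. Pixel $(r, c)$ centres map to
$x = (c + 0.5)\,dx$, $y = (r + 0.5)\,dy$; rasterization back is even-odd
point-in-polygon on pixel centres (`mgcv::in.out`). Components below
`min_area_px` (default 2 px) are dropped, which removes single-pixel noise.

**Resampling and lofting.** Closed contours are resampled equally by arc
length, starting at the vertex whose direction from the centroid points most
strongly along $+x$ — a fixed convention so independently processed rings
share an angular origin. Lofting connects consecutive rings after an
additional cyclic-offset search minimizing total inter-ring chord length
(guards against twist when the centerline wanders); each quad is split along
its shorter diagonal for better-conditioned triangles; outward orientation
is enforced by the signed volume of the capped surface. Vertex $z$ equals
the slice position exactly.

**Contour smoothing before meshing.** Membrane equilibrium divides by local
curvature, and voxel-scale wiggle in iso-contours corrupts curvature far
more than it corrupts area. On phantom geometry, meshes lofted from raw
iso-contours depress SAWS by a factor of ~2 relative to analytically smooth
meshes of the same shape, while NURBS-smoothed contours reproduce the smooth
reference. The pipeline therefore fits and resamples every contour with a
cubic NURBS before lofting (`smooth_contours = TRUE`); diameters are always
measured on the raw mask contours, where sub-pixel wiggle is harmless.

**Hydraulic diameter.** $D_h = 4A/P$ per slice (shoelace area, polygonal
perimeter); the profile's maximum is the scalar severity measure. It can be
computed from mask contours or from mesh cross-sections
(`mesh_diameter_profile()`); both are exposed since either convention is
defensible.

## NURBS refinement

Curves follow the standard rational B-spline form with clamped knot
vectors; the basis is a direct Cox–de Boor implementation (0/0 := 0).
Closed contours are fitted by least squares with chord-length
parameterization and the seam point repeated: the clamped curve then starts
and ends at the seam, closing the loop with C0 continuity. This
seam-repetition scheme was chosen over a fully periodic knot vector because
it is simpler and its seam error is directly testable (the fit reports its
maximum residual). Defaults: degree 3, `n_ctrl = max(8, points/10)`, unit
weights — the source workflow fixes none of these, so they are package
decisions tuned for contour-scale data. Edits are batch-applied and pure;
by compact support, samples farther than degree + 1 knot spans from an
edited control point are unchanged, which the tests assert to $10^{-12}$.
In the pipeline, the edit stage re-fits only slices actually addressed by
an edit, so an empty edit set is a bit-exact no-op (the "revert to
automatic" workflow).

## The synthetic phantom family

Clinical CTA data cannot ship with a package; the generators stand in for
them with geometry whose every derived quantity has a closed form:

- `make_sphere_mesh()` / `make_cylinder_mesh()` — membrane validation
  geometries with exact Laplace solutions $pR/2h$ and $pR/h$.
- `make_fusiform_phantom()` — a tube with Gaussian bulge,
  $r(z) = R_0 + \Delta R\, e^{-(z - z_0)^2 / 2s^2}$, optional sinusoidal
  centerline offset, rasterized at pixel centres; a CTA-like image
  (two-level intensity + Gaussian noise + optional bright blurred streak
  "metal artifacts" crossing the wall); and the analytic record
  ($r_{\max}$, its $z$, the radius function). Defaults emulate a moderate
  aneurysm at CT resolution: $R_0 = 11$ mm, $\Delta R = 11$ mm (44 mm peak
  diameter), 96 mm of axis, 0.85 mm pixels, 3 mm slices, noise SD 10 on a
  30/150 background/foreground intensity scale.
- `phantom_dataset()` — seeded 64 px patch pairs from randomized phantoms
  ($R_0 \in [9, 13]$, $\Delta R \in [6, 14]$ mm), roughly half containing a
  wall boundary.

What the phantoms do *not* emulate: lobulated patient-like cross-sections,
thrombus and calcification, CT physics (beam hardening, Hounsfield
calibration), bifurcations. Passing tests on phantoms therefore establishes
*algorithmic* correctness — equilibrium, geometry, convergence,
learnability — not clinical segmentation performance.

## The desk-scale dilated U-Net

The segmentation module exists to make the architecture and training
machinery concrete and testable at desk scale, not to reach clinical
accuracy. The encoder carries the dilation schedule 1 → 2 → 3 → 1 across
its four blocks (two 3×3 convolutions + ReLU each; receptive field of a
dilated convolution $RF = (k-1)d + 1$, verified in the tests against
impulse-response measurements); 2×2 max pooling between blocks;
nearest-neighbour upsampling with skip concatenation in the decoder; 1×1
sigmoid head. Depths, widths, patch size and optimizer settings are not
fixed by the source workflow and are package choices: base 16 channels
doubling per level, patch 64, batch 8, Adam 1e-3, up to 30 epochs with
early stopping on held-out Dice. The loss is BCE + (1 − soft-Dice) with
smoothing $\varepsilon = 1$ and 1:1 weighting (configurable). Convolution
forward/backward passes are compact RcppArmadillo im2col kernels with exact
gradients (checked against finite differences in the tests); training is
seeded and reproducible. Augmentation (flips, ±15° rotation, 0.9–1.1 zoom
and intensity scaling) transforms image and mask with the same geometric
map, never scaling mask intensities.

## Problem sizes and tolerances used in validation

The test suite solves the sphere band at icosphere subdivisions 3–5 (about
1,000 to 17,000 faces; interior = elements at least 3 graph rings from the
fixed boundary) and cylinders up to 64 × 32 rings, trains the U-Net on 200
patches with 60 held out, and runs the phantom pipeline at `n_circ = 64` —
sizes at which every check completes on one CPU in minutes while the
analytic errors (≤ 3% on Laplace stresses, ≤ 1% on areas, one pixel on the
maximum diameter) have clean margins. `scripts/acceptance.R` recomputes the
same quantities from scratch with a caller-supplied seed.

## Known limitations

- No bending: stresses within roughly one ring of the fixed ends are
  boundary-affected and flagged rather than trusted.
- The stabilization weight trades checkerboard suppression against fidelity
  of genuinely rough stress fields; fields with physical wavelengths near
  the mesh spacing will be smoothed.
- Percentile/mean stress conventions (weighted vs unweighted) differ across
  the literature; both modes are exposed, defaults documented above.
- The U-Net is desk-scale by design; no claim of clinical segmentation
  accuracy is made or tested.
- Open tubes only: bifurcations, thrombus, and the inner (lumen) wall are
  out of scope.
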