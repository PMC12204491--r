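Package: aaastress
Title: Material-Property-Free Wall Stress Estimation for Abdominal Aortic
    Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline from binary outer-wall segmentation masks
    of an abdominal aortic aneurysm (AAA) to patient-specific wall stress.
    Masks are converted to sub-pixel planar contours, optionally refined with
    non-uniform rational B-spline (NURBS) curve editing, lofted into an
    oriented triangular surface mesh, and fed to an inverse membrane
    equilibrium solver that recovers Cauchy wall stress from geometry and
    intraluminal pressure alone, without constitutive material properties.
    Includes a segmentation-evaluation metric suite (Dice, IoU, Matthews
    correlation, 95th-percentile Hausdorff distance and friends), a compact
    patch-based dilated U-Net for desk-scale segmentation experiments, and
    analytic phantom generators (spheres, cylinders, fusiform aneurysms) so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    mgcv,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
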