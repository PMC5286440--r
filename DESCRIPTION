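Package: thermoreg
Title: Marker-Free Longitudinal Infrared Breast Image Registration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automatic marker-free registration of longitudinal infrared
    (thermographic) breast images. Detects anatomically meaningful feature
    points (modified Harris corners with adaptive non-maximal suppression,
    and vascular-skeleton intersections obtained from Hessian-eigenvalue
    vessel enhancement, morphological thinning and junction barycenters),
    establishes correspondences by a two-tier matcher (permissive
    gradient-direction SAD relaxation matching, corrected by strict dual-map
    shape-context matching and per-side matching vectors), fits a
    thin-plate-spline deformation from the surviving control-point pairs,
    and refines control-point positions by a competitive winner-guided
    self-organizing-map search that maximizes mutual information. Includes
    a synthetic thermogram generator with known vessel skeletons and
    ground-truth deformations, and evaluation utilities (SSIM, mutual
    information, delineated-line coincidence rate, Canny-edge overlays,
    marker-error statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: ImageRegistration, Visualization, Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils-internal.R'
    'config.R'
    'io.R'
    'detect.R'
    'vessel.R'
    'matching.R'
    'tps.R'
    'som.R'
    'evaluation.R'
    'synthetic.R'
    'pipeline.R'
    'thermoreg-package.R'
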