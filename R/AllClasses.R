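#' @include AllGenerics.R
NULL

# Central S4 classes. Coordinate convention throughout the package:
# 0-based, x = column, y = row, pixel centers at integer coordinates.
# A pixel (x, y) of a ThermalImage lives at pixels(img)[y + 1, x + 1].

#' ThermalImage: a single-channel infrared intensity frame
#'
#' Thin wrapper around a numeric matrix of intensities normalized to
#' \code{[0, 1]} (rows = y, columns = x), retaining the bit depth of the
#' file it was read from as metadata. All registration entry points
#' operate on this class.
#'
#' @slot pixels numeric matrix of intensities in \code{[0, 1]}.
#' @slot bitDepth integer; bit depth of the originating file (8 or 16);
#'   purely metadata, intensities are always normalized.
#' @export
setClass("ThermalImage",
  representation(pixels = "matrix", bitDepth = "integer"),
  prototype(pixels = matrix(0, 1, 1), bitDepth = 8L))

setValidity("ThermalImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (length(p) == 0L) return("zero-size image")
  if (!all(is.finite(p))) return("intensities must be finite")
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    return("normalized intensities must lie in [0, 1]")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  TRUE
})

#' Construct a ThermalImage from a numeric matrix
#'
#' @param pixels numeric matrix in \code{[0, 1]} (rows = y, columns = x).
#' @param bitDepth nominal bit depth metadata (8 or 16).
#' @return A \linkS4class{ThermalImage}.
#' @export
ThermalImage <- function(pixels, bitDepth = 8L) {
  new("ThermalImage", pixels = pixels, bitDepth = as.integer(bitDepth))
}

#' @describeIn ThermalImage the intensity matrix.
#' @param x a \code{ThermalImage}.
#' @export
setMethod("pixels", "ThermalImage", function(x) x@pixels)

#' @describeIn ThermalImage the bit-depth metadata.
#' @export
setMethod("bitDepth", "ThermalImage", function(x) x@bitDepth)

#' @export
setMethod("dim", "ThermalImage", function(x) dim(x@pixels))

setMethod("show", "ThermalImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ThermalImage %d x %d px (%d-bit source), intensity [%.3f, %.3f]\n",
              d[2], d[1], object@bitDepth,
              min(object@pixels), max(object@pixels)))
})

#' FeaturePointSet: located landmarks with detector responses
#'
#' Corners and vascular-skeleton intersections share this container.
#' Coordinates are 0-based (x = column, y = row). The suppression radius
#' is \code{NA} until adaptive non-maximal suppression has been run.
#'
#' @slot x,y numeric; 0-based pixel coordinates.
#' @slot response numeric; Harris score or junction pixel count.
#' @slot kind character; \code{"corner"} or \code{"vessel_intersection"}.
#' @slot suppressionRadius numeric; ANMS radius in px (\code{NA} before ANMS,
#'   \code{Inf} for the global response maximum).
#' @export
setClass("FeaturePointSet",
  representation(x = "numeric", y = "numeric", response = "numeric",
                 kind = "character", suppressionRadius = "numeric"))

setValidity("FeaturePointSet", function(object) {
  n <- length(object@x)
  if (length(object@y) != n || length(object@response) != n ||
      length(object@kind) != n || length(object@suppressionRadius) != n)
    return("all slots must have equal length")
  if (n > 0 && !all(is.finite(object@response)))
    return("responses must be finite")
  if (!all(object@kind %in% c("corner", "vessel_intersection")))
    return("kind must be 'corner' or 'vessel_intersection'")
  TRUE
})

#' Construct a FeaturePointSet
#'
#' @param x,y 0-based coordinates.
#' @param response detector responses.
#' @param kind point kind, recycled.
#' @param suppressionRadius ANMS radii (NA before ANMS).
#' @return A \linkS4class{FeaturePointSet}.
#' @export
FeaturePointSet <- function(x = numeric(), y = numeric(),
                            response = numeric(),
                            kind = "corner",
                            suppressionRadius = rep(NA_real_, length(x))) {
  new("FeaturePointSet", x = as.numeric(x), y = as.numeric(y),
      response = as.numeric(response),
      kind = rep_len(kind, length(x)),
      suppressionRadius = as.numeric(suppressionRadius))
}

#' @export
setMethod("length", "FeaturePointSet", function(x) length(x@x))

#' @describeIn FeaturePointSet n x 2 matrix of (x, y) coordinates.
#' @param x a \code{FeaturePointSet}.
#' @export
setMethod("coords", "FeaturePointSet", function(x)
  cbind(x = x@x, y = x@y))

#' @describeIn FeaturePointSet detector responses.
#' @export
setMethod("responses", "FeaturePointSet", function(x) x@response)

#' @describeIn FeaturePointSet point kinds.
#' @export
setMethod("pointKind", "FeaturePointSet", function(x) x@kind)

#' @describeIn FeaturePointSet ANMS suppression radii.
#' @export
setMethod("suppressionRadius", "FeaturePointSet", function(x)
  x@suppressionRadius)

#' @export
setMethod("[", "FeaturePointSet", function(x, i, j, ..., drop = TRUE) {
  new("FeaturePointSet", x = x@x[i], y = x@y[i], response = x@response[i],
      kind = x@kind[i], suppressionRadius = x@suppressionRadius[i])
})

#' @export
setMethod("as.data.frame", "FeaturePointSet", function(x, ...) {
  data.frame(x = x@x, y = x@y, response = x@response, kind = x@kind,
             suppression_radius = x@suppressionRadius)
})

setMethod("show", "FeaturePointSet", function(object) {
  cat(sprintf("FeaturePointSet with %d points (%d corner, %d vessel_intersection)\n",
              length(object@x), sum(object@kind == "corner"),
              sum(object@kind == "vessel_intersection")))
})

#' Concatenate feature point sets
#' @param a,b \linkS4class{FeaturePointSet} objects.
#' @export
concatFeaturePoints <- function(a, b) {
  new("FeaturePointSet",
      x = c(a@x, b@x), y = c(a@y, b@y),
      response = c(a@response, b@response),
      kind = c(a@kind, b@kind),
      suppressionRadius = c(a@suppressionRadius, b@suppressionRadius))
}

#' MatchSet: ordered source/target correspondences
#'
#' One row per correspondence; also serves as the ControlPointPairs
#' container anchoring the TPS warp. Provenance records which matching
#' tier produced each pair.
#'
#' @slot xs,ys source-side 0-based coordinates.
#' @slot xt,yt target-side 0-based coordinates.
#' @slot cost matching cost (SAD or shape-context chi-squared).
#' @slot provenance one of \code{"strict"}, \code{"relaxed"},
#'   \code{"relaxed_revised"} per pair.
#' @export
setClass("MatchSet",
  representation(xs = "numeric", ys = "numeric", xt = "numeric",
                 yt = "numeric", cost = "numeric", provenance = "character"))

setValidity("MatchSet", function(object) {
  n <- length(object@xs)
  if (length(object@ys) != n || length(object@xt) != n ||
      length(object@yt) != n || length(object@cost) != n ||
      length(object@provenance) != n)
    return("all slots must have equal length")
  if (!all(object@provenance %in% c("strict", "relaxed", "relaxed_revised")))
    return("provenance must be strict | relaxed | relaxed_revised")
  if (n > 0 && any(is.na(object@cost)))
    return("costs must not be NA")
  for (pv in unique(object@provenance)) {
    sel <- object@provenance == pv
    if (anyDuplicated(cbind(object@xs[sel], object@ys[sel])) ||
        anyDuplicated(cbind(object@xt[sel], object@yt[sel])))
      return(sprintf("matches must be one-to-one within tier '%s'", pv))
  }
  TRUE
})

#' Construct a MatchSet
#' @param xs,ys,xt,yt coordinates (0-based).
#' @param cost per-pair matching cost.
#' @param provenance matching tier label, recycled.
#' @return A \linkS4class{MatchSet}.
#' @export
MatchSet <- function(xs = numeric(), ys = numeric(), xt = numeric(),
                     yt = numeric(), cost = numeric(),
                     provenance = character()) {
  if (length(provenance) == 1L) provenance <- rep(provenance, length(xs))
  new("MatchSet", xs = as.numeric(xs), ys = as.numeric(ys),
      xt = as.numeric(xt), yt = as.numeric(yt), cost = as.numeric(cost),
      provenance = provenance)
}

#' @export
setMethod("length", "MatchSet", function(x) length(x@xs))

#' @describeIn MatchSet n x 2 matrix of source-side points.
#' @param x a \code{MatchSet}.
#' @export
setMethod("sourcePoints", "MatchSet", function(x) cbind(x = x@xs, y = x@ys))

#' @describeIn MatchSet n x 2 matrix of target-side points.
#' @export
setMethod("targetPoints", "MatchSet", function(x) cbind(x = x@xt, y = x@yt))

#' @describeIn MatchSet per-pair costs.
#' @export
setMethod("matchCosts", "MatchSet", function(x) x@cost)

#' @describeIn MatchSet per-pair tier labels.
#' @export
setMethod("provenance", "MatchSet", function(x) x@provenance)

#' @export
setMethod("[", "MatchSet", function(x, i, j, ..., drop = TRUE) {
  new("MatchSet", xs = x@xs[i], ys = x@ys[i], xt = x@xt[i], yt = x@yt[i],
      cost = x@cost[i], provenance = x@provenance[i])
})

#' @export
setMethod("as.data.frame", "MatchSet", function(x, ...) {
  data.frame(id = seq_along(x@xs) - 1L,
             x_source = x@xs, y_source = x@ys,
             x_target = x@xt, y_target = x@yt,
             cost = x@cost, provenance = x@provenance)
})

setMethod("show", "MatchSet", function(object) {
  tab <- table(factor(object@provenance,
                      c("strict", "relaxed", "relaxed_revised")))
  cat(sprintf("MatchSet with %d pairs (strict %d, relaxed %d, relaxed_revised %d)\n",
              length(object@xs), tab[1], tab[2], tab[3]))
})

#' TPSModel: a fitted thin-plate-spline map
#'
#' Coefficients of the map (x, y) -> (x', y') with
#' \eqn{x' = a_1 + a_x x + a_y y + \sum_j w_j U(r_j)},
#' \eqn{U(r) = r^2 \log r^2}, and \eqn{r_j} the distance to the j-th
#' anchor. Coefficient vectors are ordered \code{(w_1..w_n, a1, ax, ay)}.
#'
#' @slot anchors n x 2 matrix of anchor (input-side) points.
#' @slot coefX,coefY length n + 3 coefficient vectors for x' and y'.
#' @slot lambda regularization weight used at fit time.
#' @export
setClass("TPSModel",
  representation(anchors = "matrix", coefX = "numeric", coefY = "numeric",
                 lambda = "numeric"))

setValidity("TPSModel", function(object) {
  n <- nrow(object@anchors)
  if (ncol(object@anchors) != 2) return("anchors must be n x 2")
  if (length(object@coefX) != n + 3 || length(object@coefY) != n + 3)
    return("coefficient vectors must have length n + 3")
  if (!all(is.finite(object@coefX)) || !all(is.finite(object@coefY)))
    return("coefficients must be finite")
  # orthogonality side conditions: sum w = sum w x = sum w y = 0
  for (cf in list(object@coefX, object@coefY)) {
    w <- cf[seq_len(n)]
    s <- c(sum(w), sum(w * object@anchors[, 1]), sum(w * object@anchors[, 2]))
    if (any(abs(s) > 1e-6 * max(1, max(abs(w)))))
      return("non-affine weights violate TPS side conditions")
  }
  TRUE
})

#' @describeIn TPSModel the anchor points.
#' @param x a \code{TPSModel}.
#' @export
setMethod("anchors", "TPSModel", function(x) x@anchors)

setMethod("show", "TPSModel", function(object) {
  n <- nrow(object@anchors)
  be <- tpsBendingEnergy(object)
  cat(sprintf("TPSModel with %d anchors (lambda = %g, bending energy %.4g)\n",
              n, object@lambda, be))
})

#' SyntheticScene: a generated IR-like test scene
#'
#' Bright Gaussian-profile vessel ridges on a smooth warm background
#' blob; the vessel centerlines and branch junctions are stored exactly
#' as generated and serve as ground truth for the detectors.
#'
#' @slot seed integer generator seed.
#' @slot width,height scene size in px.
#' @slot background list: center (x, y), sd (sx, sy), angle, peak.
#' @slot branches list of polylines (m x 2 matrices of 0-based (x, y))
#'   each with attributes \code{width} (px) and \code{brightness}.
#' @slot junctionsXY k x 2 matrix of true branch-point coordinates.
#' @slot noiseSigma additive Gaussian noise sd.
#' @slot intensityOffset global offset applied to the second time point.
#' @export
setClass("SyntheticScene",
  representation(seed = "integer", width = "integer", height = "integer",
                 background = "list", branches = "list",
                 junctionsXY = "matrix", noiseSigma = "numeric",
                 intensityOffset = "numeric"))

setValidity("SyntheticScene", function(object) {
  if (object@width < 64L || object@height < 64L)
    return("degenerate scene size (< 64 px)")
  if (nrow(object@junctionsXY) < 1L)
    return("scene must record at least one vessel junction")
  TRUE
})

#' @describeIn SyntheticScene true junction coordinates (k x 2).
#' @param x a \code{SyntheticScene}.
#' @export
setMethod("junctions", "SyntheticScene", function(x) x@junctionsXY)

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene %d x %d px, %d vessel branches, %d junctions (seed %d)\n",
              object@width, object@height, length(object@branches),
              nrow(object@junctionsXY), object@seed))
})

#' GroundTruthWarp: a known smooth deformation
#'
#' Wraps a vectorized mapping \code{(x, y) -> (x', y')} together with its
#' family and the bound on its displacement magnitude.
#'
#' @slot family \code{"identity"}, \code{"translation"} or \code{"tps"}.
#' @slot fun function taking an n x 2 matrix, returning an n x 2 matrix.
#' @slot maxDisplacement stated bound on \eqn{\|warp(p) - p\|} in px.
#' @export
setClass("GroundTruthWarp",
  representation(family = "character", fun = "function",
                 maxDisplacement = "numeric"))

setValidity("GroundTruthWarp", function(object) {
  if (!object@family %in% c("identity", "translation", "tps"))
    return("family must be identity | translation | tps")
  TRUE
})

#' @describeIn GroundTruthWarp apply the warp to an n x 2 point matrix.
#' @param warp a \code{GroundTruthWarp}.
#' @param pts n x 2 matrix of (x, y).
#' @export
setMethod("applyWarp", "GroundTruthWarp", function(warp, pts) {
  pts <- rbind(pts)
  warp@fun(pts)
})

setMethod("show", "GroundTruthWarp", function(object) {
  cat(sprintf("GroundTruthWarp (%s), max displacement %.2f px\n",
              object@family, object@maxDisplacement))
})

#' SOMParams: schedules of the winner-guided refinement
#'
#' @slot gridSize odd lattice side G; candidates per point = G^2.
#' @slot gridSpacing lattice spacing s in px.
#' @slot eta0 initial learning rate in (0, 1].
#' @slot sig0 initial neighborhood parameter in px.
#' @slot iMax total iteration (sweep) budget.
#' @slot miBins joint-histogram bins for mutual information.
#' @slot stabilityWindow consecutive all-centers iterations declaring
#'   convergence.
#' @slot miTol noise margin in nats: a candidate unit must beat the
#'   center unit's MI by more than this to win, so joint-histogram
#'   sampling noise cannot drift control points along flat MI.
#' @slot miStride pixel stride of the subsampled grid used to score
#'   candidate units; the committed global MI always uses the full
#'   grid.
#' @slot trustRadius maximum distance (px) a control point may travel
#'   from its original matched position; candidate units beyond it are
#'   not offered. \code{Inf} disables the bound.
#' @export
setClass("SOMParams",
  representation(gridSize = "integer", gridSpacing = "numeric",
                 eta0 = "numeric", sig0 = "numeric", iMax = "integer",
                 miBins = "integer", stabilityWindow = "integer",
                 miTol = "numeric", miStride = "integer",
                 trustRadius = "numeric"))

setValidity("SOMParams", function(object) {
  if (object@gridSize < 3L || object@gridSize %% 2L == 0L)
    return("gridSize must be odd and >= 3")
  if (object@gridSpacing < 1) return("gridSpacing must be >= 1 px")
  if (object@eta0 <= 0 || object@eta0 > 1) return("eta0 must be in (0, 1]")
  if (object@sig0 <= 0) return("sig0 must be positive")
  if (object@iMax < object@stabilityWindow)
    return("iMax must be >= stabilityWindow")
  if (object@miBins < 2L) return("miBins must be >= 2")
  if (object@miTol < 0) return("miTol must be >= 0")
  if (object@miStride < 1L) return("miStride must be >= 1")
  if (object@trustRadius <= 0) return("trustRadius must be positive")
  TRUE
})

#' Construct SOMParams
#' @param gridSize,gridSpacing,eta0,sig0,iMax,miBins,stabilityWindow,miTol,miStride,trustRadius
#'   see \linkS4class{SOMParams}.
#' @export
somParams <- function(gridSize = 5L, gridSpacing = 2, eta0 = 0.5,
                      sig0 = 10, iMax = 30L, miBins = 32L,
                      stabilityWindow = 3L, miTol = 0.02,
                      miStride = 2L, trustRadius = 6) {
  new("SOMParams", gridSize = as.integer(gridSize),
      gridSpacing = gridSpacing, eta0 = eta0, sig0 = sig0,
      iMax = as.integer(iMax), miBins = as.integer(miBins),
      stabilityWindow = as.integer(stabilityWindow), miTol = miTol,
      miStride = as.integer(miStride), trustRadius = trustRadius)
}

setMethod("show", "SOMParams", function(object) {
  cat(sprintf("SOMParams: %dx%d units at %g px, eta0 %g, Sig0 %g px, iMax %d, %d MI bins\n",
              object@gridSize, object@gridSize, object@gridSpacing,
              object@eta0, object@sig0, object@iMax, object@miBins))
})

#' RegistrationResult: the output of the full pipeline
#'
#' @slot warpedSource the source image resampled into target geometry.
#' @slot controlPairs the final control-point pairs.
#' @slot forwardModel TPS mapping source -> target coordinates.
#' @slot backwardModel TPS mapping target -> source, used for resampling.
#' @slot metrics named list: ssim_before/after, mi_before/after.
#' @slot somTrace per-iteration committed MI of the refinement.
#' @slot converged logical; SOM stability reached within the budget.
#' @slot stageLog data.frame of per-stage surviving point counts.
#' @export
setClass("RegistrationResult",
  representation(warpedSource = "ThermalImage", controlPairs = "MatchSet",
                 forwardModel = "TPSModel", backwardModel = "TPSModel",
                 metrics = "list", somTrace = "numeric",
                 converged = "logical", stageLog = "data.frame"))

setValidity("RegistrationResult", function(object) {
  need <- c("ssim_before", "ssim_after", "mi_before", "mi_after")
  if (!all(need %in% names(object@metrics)))
    return("metrics must contain ssim_before/after and mi_before/after")
  v <- unlist(object@metrics[need])
  if (!all(is.finite(v))) return("metrics must be finite")
  TRUE
})

#' @describeIn RegistrationResult the warped source image.
#' @param x a \code{RegistrationResult}.
#' @export
setMethod("warpedSource", "RegistrationResult", function(x) x@warpedSource)

#' @describeIn RegistrationResult the final control-point pairs.
#' @export
setMethod("controlPairs", "RegistrationResult", function(x) x@controlPairs)

#' @describeIn RegistrationResult the metric list.
#' @export
setMethod("registrationMetrics", "RegistrationResult", function(x) x@metrics)

#' @describeIn RegistrationResult committed MI per SOM iteration.
#' @export
setMethod("somTrace", "RegistrationResult", function(x) x@somTrace)

#' @describeIn RegistrationResult the source-to-target TPS.
#' @export
setMethod("forwardModel", "RegistrationResult", function(x) x@forwardModel)

#' @describeIn RegistrationResult the target-to-source TPS.
#' @export
setMethod("backwardModel", "RegistrationResult", function(x) x@backwardModel)

setMethod("show", "RegistrationResult", function(object) {
  m <- object@metrics
  cat(sprintf(paste0(
    "RegistrationResult: %d control pairs, SSIM %.3f -> %.3f, ",
    "MI %.3f -> %.3f nats (%s)\n"),
    length(object@controlPairs), m$ssim_before, m$ssim_after,
    m$mi_before, m$mi_after,
    if (object@converged) "SOM converged" else "SOM budget reached"))
})
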