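# Vascular-intersection detection: Hessian bright-ridge enhancement,
# Otsu masking, morphological thinning, junction labeling and barycenters.

#' Hessian bright-ridge vessel enhancement
#'
#' Computes the scale-normalized Hessian at scale \code{sigmaV} and a
#' Frangi-style bright-ridge likelihood: high where the large-magnitude
#' eigenvalue \eqn{\lambda_2} is strongly negative (bright tubular
#' structure) and the other eigenvalue is near zero. The binary vessel
#' mask thresholds the likelihood by Otsu's method computed on its
#' nonzero values.
#'
#' @param img a \linkS4class{ThermalImage} or numeric matrix.
#' @param sigmaV Hessian scale in px (about half the vessel width).
#' @param beta blob/ridge discrimination parameter of the likelihood.
#' @return list with \code{likelihood} (matrix in [0, 1]) and
#'   \code{mask} (logical matrix).
#' @export
vesselMap <- function(img, sigmaV = 2, beta = 0.5) {
  stopifnot(sigmaV > 0)
  m <- .as_pixels(img)
  ker <- .hessian_kernels(sigmaV)
  hxx <- .filter2(m, ker$xx)
  hyy <- .filter2(m, ker$yy)
  hxy <- .filter2(m, ker$xy)
  # eigenvalues of [[hxx, hxy], [hxy, hyy]], ordered |l1| <= |l2|
  tmp <- sqrt((hxx - hyy)^2 + 4 * hxy^2)
  e1 <- (hxx + hyy + tmp) / 2
  e2 <- (hxx + hyy - tmp) / 2
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)   # small magnitude
  l2 <- ifelse(swap, e1, e2)   # large magnitude
  S2 <- l1^2 + l2^2
  if (max(S2) < 1e-10)         # flat image: convolution roundoff only
    return(list(likelihood = matrix(0, nrow(m), ncol(m)),
                mask = matrix(FALSE, nrow(m), ncol(m))))
  c2 <- max(S2) / 4            # c = half the max Frobenius norm
  rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  lik <- ifelse(l2 < 0,
                exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2))),
                0)
  if (max(lik) > 0) lik <- lik / max(lik)
  nz <- lik[lik > 0]
  thr <- if (length(nz)) .otsu_threshold(nz) else Inf
  list(likelihood = lik, mask = lik >= thr & lik > 0)
}

#' Morphological thinning to a 1-px skeleton
#'
#' Zhang-Suen thinning with a connectivity-preserving cleanup pass so no
#' skeleton pixel belongs to a fully-set 2x2 block. Connectivity of each
#' 8-connected component is preserved.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix: the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- mask
  if (is(m, "ThermalImage")) m <- pixels(m) > 0
  storage.mode(m) <- "integer"
  cpp_thin(m) > 0L
}

#' Raw junction pixels of a thin skeleton
#'
#' A skeleton pixel is a raw junction iff at least 3 distinct skeleton
#' branches leave it: its Rutovitz crossing number (0-to-1 transitions
#' along the circular 8-neighborhood sequence) is at least 3. On a thin
#' skeleton this refines the naive ">= 3 set neighbors" count, which
#' also fires on 8-connected staircase pixels of diagonal lines.
#' Junction pixels are labeled into 8-connected clusters for barycenter
#' extraction.
#'
#' @param skel logical skeleton matrix (from \code{\link{skeletonize}}).
#' @return data.frame with columns \code{x}, \code{y} (0-based) and
#'   \code{label} (cluster id); zero rows when there are no junctions.
#' @export
skeletonIntersections <- function(skel) {
  s <- skel * 1
  H <- nrow(s); W <- ncol(s)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- s
  sh <- function(dy, dx) pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  # circular neighbor sequence N, NE, E, SE, S, SW, W, NW
  nb <- list(sh(-1, 0), sh(-1, 1), sh(0, 1), sh(1, 1),
             sh(1, 0), sh(1, -1), sh(0, -1), sh(-1, -1))
  crossing <- matrix(0, H, W)
  for (k in seq_along(nb)) {
    nxt <- nb[[if (k == length(nb)) 1 else k + 1]]
    crossing <- crossing + (nb[[k]] == 0 & nxt == 1)
  }
  junc <- skel & crossing >= 3
  if (!any(junc))
    return(data.frame(x = numeric(), y = numeric(), label = integer()))
  lab <- .label8(junc)
  idx <- which(junc, arr.ind = TRUE)
  # which(..., arr.ind) and matrix subsetting share column-major order
  data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1, label = lab[junc])
}

# 8-connected labeling; EBImage::bwlabel is 4-connected, so bridge
# diagonals by dilating with a 3x3 box, labeling, and masking back
.label8 <- function(mask) {
  m <- mask * 1
  grown <- EBImage::dilate(m, EBImage::makeBrush(3, "box"))
  lab <- EBImage::bwlabel(grown)
  lab <- round(as.matrix(lab))
  lab[!mask] <- 0L
  lab
}

#' Junction barycenters
#'
#' Merges junction pixel clusters whose centroids lie within
#' \code{mergeRadius} of one another (single linkage) and returns one
#' representative vascular intersection per merged cluster: the
#' pixel-count-weighted centroid, with response = total pixel count.
#'
#' @param raw data.frame from \code{\link{skeletonIntersections}}.
#' @param mergeRadius merge radius in px (>= 1).
#' @return A \linkS4class{FeaturePointSet} of kind
#'   \code{"vessel_intersection"}.
#' @export
junctionBarycenters <- function(raw, mergeRadius = 8) {
  stopifnot(mergeRadius >= 1)
  if (nrow(raw) == 0L)
    return(FeaturePointSet(kind = character()))
  cl <- split(raw[c("x", "y")], raw$label)
  cx <- vapply(cl, function(d) mean(d$x), 0)
  cy <- vapply(cl, function(d) mean(d$y), 0)
  np <- vapply(cl, nrow, 0L)
  k <- length(cl)
  grp <- if (k == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(cbind(cx, cy)), "single"),
                  h = mergeRadius)
  xs <- tapply(cx * np, grp, sum) / tapply(np, grp, sum)
  ys <- tapply(cy * np, grp, sum) / tapply(np, grp, sum)
  ns <- tapply(np, grp, sum)
  FeaturePointSet(x = as.numeric(xs), y = as.numeric(ys),
                  response = as.numeric(ns), kind = "vessel_intersection")
}

#' Detect all registration features of one frame
#'
#' Runs the corner detector (with ANMS) and the vascular-intersection
#' detector and returns their union together with the intermediate maps
#' needed by the shape-context matcher.
#'
#' @param img a \linkS4class{ThermalImage}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return list: \code{points} (\linkS4class{FeaturePointSet}),
#'   \code{skeleton} (logical matrix), \code{vesselMask},
#'   \code{heatMask} (Otsu threshold of the intensity image).
#' @export
detectFeatures <- function(img, config = pipelineConfig()) {
  m <- .as_pixels(img)
  corners <- harrisCorners(img, sigma = config[["harris_sigma"]],
                           k = config[["harris_k"]],
                           relThreshold = config[["harris_rel_threshold"]])
  if (length(corners) > 0L)
    corners <- anms(corners, config[["anms_n"]], config[["anms_c_robust"]])
  vm <- vesselMap(img, sigmaV = config[["vessel_sigma"]])
  skel <- skeletonize(vm$mask)
  raw <- skeletonIntersections(skel)
  juncs <- junctionBarycenters(raw, config[["junction_merge_radius"]])
  heat <- m >= .otsu_threshold(as.numeric(m))
  list(points = concatFeaturePoints(corners, juncs),
       skeleton = skel, vesselMask = vm$mask, heatMask = heat)
}
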