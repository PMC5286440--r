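# Synthetic IR-like scenes: a warm anisotropic Gaussian background blob
# carrying bright Gaussian-profile vessel ridges with known centerlines
# and branch junctions, plus known smooth deformations between the two
# time points. Everything is a pure function of (scene, warp, seeds).

#' Generate a synthetic IR-like scene
#'
#' Places \code{nJunctions} well-separated branch points in the image
#' interior and grows three gently curving vessel branches from each;
#' the true junction coordinates and centerline polylines are stored
#' exactly. The background emulates the warm breast surface as an
#' anisotropic Gaussian blob.
#'
#' @param seed integer; the scene is a pure function of it.
#' @param width,height scene size in px (>= 64).
#' @param nJunctions branch points to place (>= 1).
#' @param branchWidth vessel ridge width in px (2-5).
#' @param noiseSigma additive Gaussian noise sd used at render time.
#' @param intensityOffset global intensity offset of the second time
#'   point (different basic body temperature).
#' @return A \linkS4class{SyntheticScene}.
#' @examples
#' sc <- generateScene(0)
#' nrow(junctions(sc))
#' @export
generateScene <- function(seed, width = 160L, height = 128L,
                          nJunctions = 3L, branchWidth = 3,
                          noiseSigma = 0.01, intensityOffset = 0.05) {
  if (width < 64L || height < 64L)
    stop("degenerate scene size (< 64 px)")
  stopifnot(nJunctions >= 1, branchWidth >= 2, branchWidth <= 5)
  with_seed(as.integer(seed), {
    margin <- 24
    juncs <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(juncs) < nJunctions && tries < 500) {
      cand <- c(stats::runif(1, margin, width - 1 - margin),
                stats::runif(1, margin, height - 1 - margin))
      if (nrow(juncs) == 0 ||
          min(sqrt((juncs[, 1] - cand[1])^2 + (juncs[, 2] - cand[2])^2)) > 45)
        juncs <- rbind(juncs, cand)
      tries <- tries + 1
    }
    branches <- list()
    for (k in seq_len(nrow(juncs))) {
      base <- stats::runif(1, 0, 2 * pi)
      for (b in 0:2) {
        ang <- base + b * 2 * pi / 3 + stats::runif(1, -0.25, 0.25)
        len <- stats::runif(1, 35, 55)
        pts <- matrix(juncs[k, ], 1, 2)
        cur <- juncs[k, ]
        a <- ang
        for (stp in seq_len(ceiling(len / 2))) {
          a <- a + stats::runif(1, -0.07, 0.07)
          cur <- cur + 2 * c(cos(a), sin(a))
          if (cur[1] < 3 || cur[1] > width - 4 ||
              cur[2] < 3 || cur[2] > height - 4) break
          pts <- rbind(pts, cur)
        }
        if (nrow(pts) < 4) next
        attr(pts, "width") <- branchWidth
        attr(pts, "brightness") <- stats::runif(1, 0.28, 0.38)
        branches[[length(branches) + 1]] <- pts
      }
    }
    # distinctive mottled heat pattern: warm/cool spots that deform
    # with the scene geometry (the subject-specific thermal signature)
    nSpots <- 45L
    spots <- cbind(x = stats::runif(nSpots, 4, width - 5),
                   y = stats::runif(nSpots, 4, height - 5),
                   sd = stats::runif(nSpots, 3, 10),
                   amp = stats::runif(nSpots, -0.13, 0.15))
    bg <- list(center = c(width / 2 + stats::runif(1, -8, 8),
                          height / 2 + stats::runif(1, -6, 6)),
               sd = c(0.32 * width, 0.38 * height),
               angle = stats::runif(1, -0.3, 0.3),
               peak = 0.5,
               spots = spots)
    new("SyntheticScene", seed = as.integer(seed),
        width = as.integer(width), height = as.integer(height),
        background = bg, branches = branches,
        junctionsXY = unname(juncs), noiseSigma = noiseSigma,
        intensityOffset = intensityOffset)
  })
}

# rasterize scene geometry (optionally pre-warped) into an intensity
# matrix; deterministic given noiseSeed
.render_scene <- function(scene, warp = NULL, offset = 0, noiseSeed = NULL) {
  W <- scene@width; H <- scene@height
  bg <- scene@background
  ctr <- bg$center
  if (!is.null(warp)) ctr <- drop(applyWarp(warp, rbind(ctr)))
  ca <- cos(bg$angle); sa <- sin(bg$angle)
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE) - ctr[1]
  ys <- matrix(0:(H - 1), H, W) - ctr[2]
  u <- (ca * xs + sa * ys) / bg$sd[1]
  v <- (-sa * xs + ca * ys) / bg$sd[2]
  img <- bg$peak * exp(-(u^2 + v^2) / 2)
  if (!is.null(bg$spots)) {
    sp <- bg$spots
    ctrs <- sp[, c("x", "y"), drop = FALSE]
    if (!is.null(warp)) ctrs <- applyWarp(warp, ctrs)
    gx <- matrix(0:(W - 1), H, W, byrow = TRUE)
    gy <- matrix(0:(H - 1), H, W)
    for (k in seq_len(nrow(sp))) {
      d2 <- (gx - ctrs[k, 1])^2 + (gy - ctrs[k, 2])^2
      img <- img + sp[k, "amp"] * exp(-d2 / (2 * sp[k, "sd"]^2))
    }
  }
  vessel <- matrix(0, H, W)
  for (br in scene@branches) {
    pts <- br
    if (!is.null(warp)) pts <- applyWarp(warp, br)
    sw <- attr(br, "width") / 2
    bright <- attr(br, "brightness")
    # resample the polyline at ~0.5 px spacing
    seg <- diff(pts)
    lens <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(lens))
    tt <- seq(0, cum[length(cum)], by = 0.5)
    px <- stats::approx(cum, pts[, 1], tt)$y
    py <- stats::approx(cum, pts[, 2], tt)$y
    hw <- ceiling(3 * sw)
    for (s in seq_along(px)) {
      x0 <- round(px[s]); y0 <- round(py[s])
      lox <- max(0, x0 - hw); hix <- min(W - 1, x0 + hw)
      loy <- max(0, y0 - hw); hiy <- min(H - 1, y0 + hw)
      if (lox > hix || loy > hiy) next
      cx <- lox:hix
      cy <- loy:hiy
      d2 <- outer((cy - py[s])^2, (cx - px[s])^2, "+")
      patch <- bright * exp(-d2 / (2 * sw^2))
      sub <- vessel[cy + 1, cx + 1, drop = FALSE]
      vessel[cy + 1, cx + 1] <- pmax(sub, patch)
    }
  }
  img <- img + vessel + offset
  if (!is.null(noiseSeed) && scene@noiseSigma > 0)
    img <- img + with_seed(as.integer(noiseSeed),
                           matrix(stats::rnorm(H * W, 0, scene@noiseSigma),
                                  H, W))
  pmin(pmax(img, 0), 1)
}

#' Render the source frame of a scene
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param noiseSeed seed of the additive noise (\code{NULL} = no
#'   noise).
#' @return A \linkS4class{ThermalImage}.
#' @export
renderScene <- function(scene, noiseSeed = NULL) {
  ThermalImage(.render_scene(scene, noiseSeed = noiseSeed))
}

#' Binary centerline raster of a scene's vessel tree
#'
#' The generated polylines stamped into a logical matrix; the
#' ground-truth counterpart of the detected skeleton.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param warp optional \linkS4class{GroundTruthWarp} applied to the
#'   geometry first.
#' @return logical matrix.
#' @export
sceneCenterlines <- function(scene, warp = NULL) {
  W <- scene@width; H <- scene@height
  out <- matrix(FALSE, H, W)
  for (br in scene@branches) {
    pts <- br
    if (!is.null(warp)) pts <- applyWarp(warp, br)
    seg <- diff(pts)
    cum <- c(0, cumsum(sqrt(rowSums(seg^2))))
    tt <- seq(0, cum[length(cum)], by = 0.5)
    px <- round(stats::approx(cum, pts[, 1], tt)$y)
    py <- round(stats::approx(cum, pts[, 2], tt)$y)
    ok <- px >= 0 & px < W & py >= 0 & py < H
    out[cbind(py[ok] + 1, px[ok] + 1)] <- TRUE
  }
  out
}

#' Identity ground-truth warp
#' @return A \linkS4class{GroundTruthWarp}.
#' @export
identityWarp <- function() {
  new("GroundTruthWarp", family = "identity", fun = function(p) p,
      maxDisplacement = 0)
}

#' Pure-translation ground-truth warp
#' @param tx,ty translation in px.
#' @return A \linkS4class{GroundTruthWarp}.
#' @export
translationWarp <- function(tx, ty) {
  new("GroundTruthWarp", family = "translation",
      fun = function(p) cbind(p[, 1] + tx, p[, 2] + ty),
      maxDisplacement = sqrt(tx^2 + ty^2))
}

#' TPS ground-truth warp from anchor displacements
#'
#' @param anchorPts n x 2 anchor matrix (n >= 4).
#' @param displacements n x 2 matrix of anchor displacements.
#' @return A \linkS4class{GroundTruthWarp} wrapping the interpolating
#'   TPS through the displaced anchors.
#' @export
tpsWarp <- function(anchorPts, displacements) {
  model <- fitTPS(anchorPts, anchorPts + displacements, 0)
  new("GroundTruthWarp", family = "tps",
      fun = function(p) tpsApply(model, p),
      maxDisplacement = max(sqrt(rowSums(displacements^2))))
}

#' Random smooth TPS warp on a 3 x 3 anchor grid
#'
#' Anchor displacements drawn uniformly in the disc of radius
#' \code{maxDisplacement}; a pure function of \code{seed}.
#'
#' @param seed integer.
#' @param width,height image size the warp is meant for.
#' @param maxDisplacement bound on anchor displacement norms, px.
#' @return A \linkS4class{GroundTruthWarp}.
#' @export
randomSmoothWarp <- function(seed, width = 160L, height = 128L,
                             maxDisplacement = 15) {
  with_seed(as.integer(seed), {
    gx <- seq(0.1, 0.9, length.out = 3) * (width - 1)
    gy <- seq(0.1, 0.9, length.out = 3) * (height - 1)
    anchorPts <- as.matrix(expand.grid(x = gx, y = gy))
    n <- nrow(anchorPts)
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- maxDisplacement * sqrt(stats::runif(n))
    tpsWarp(anchorPts, cbind(rad * cos(ang), rad * sin(ang)))
  })
}

#' Render a registered image pair with ground truth
#'
#' The source frame renders the scene as generated; the target frame
#' renders the scene geometry pushed through the warp, with the
#' scene's global intensity offset and independent noise. Landmarks
#' (junctions plus points sampled along the centerlines) are emitted as
#' exact pairs under the warp.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param warp a \linkS4class{GroundTruthWarp}; max displacement must
#'   not exceed a quarter of the smaller image side, and the warp must
#'   not fold (negative Jacobian) on the image domain.
#' @param noiseSeeds length-2 integer vector: noise seeds of the two
#'   frames.
#' @return list: \code{source}, \code{target}
#'   (\linkS4class{ThermalImage}), \code{landmarks} (list with
#'   \code{source} and \code{target} n x 2 matrices).
#' @export
renderPair <- function(scene, warp, noiseSeeds = scene@seed + c(11L, 23L)) {
  stopifnot(is(scene, "SyntheticScene"), is(warp, "GroundTruthWarp"))
  if (warp@maxDisplacement > min(scene@width, scene@height) / 4)
    stop("warp displacement exceeds a quarter of the image size")
  .check_no_folding(warp, scene@width, scene@height)
  src <- .render_scene(scene, warp = NULL, offset = 0,
                       noiseSeed = noiseSeeds[1])
  tgt <- .render_scene(scene, warp = warp,
                       offset = scene@intensityOffset,
                       noiseSeed = noiseSeeds[2])
  lmS <- junctions(scene)
  for (br in scene@branches) {
    idx <- seq(5, nrow(br) - 2, by = 8)
    if (length(idx)) lmS <- rbind(lmS, br[idx, , drop = FALSE])
  }
  lmT <- applyWarp(warp, lmS)
  inb <- lmT[, 1] >= 0 & lmT[, 1] <= scene@width - 1 &
    lmT[, 2] >= 0 & lmT[, 2] <= scene@height - 1
  list(source = ThermalImage(src), target = ThermalImage(tgt),
       landmarks = list(source = lmS[inb, , drop = FALSE],
                        target = lmT[inb, , drop = FALSE]))
}

# reject warps that fold: sample the Jacobian determinant numerically
.check_no_folding <- function(warp, width, height, spacing = 8) {
  gx <- seq(0, width - 1, by = spacing)
  gy <- seq(0, height - 1, by = spacing)
  g <- as.matrix(expand.grid(x = gx, y = gy))
  h <- 0.5
  fx1 <- applyWarp(warp, cbind(g[, 1] + h, g[, 2]))
  fx0 <- applyWarp(warp, cbind(g[, 1] - h, g[, 2]))
  fy1 <- applyWarp(warp, cbind(g[, 1], g[, 2] + h))
  fy0 <- applyWarp(warp, cbind(g[, 1], g[, 2] - h))
  J11 <- (fx1[, 1] - fx0[, 1]) / (2 * h)
  J21 <- (fx1[, 2] - fx0[, 2]) / (2 * h)
  J12 <- (fy1[, 1] - fy0[, 1]) / (2 * h)
  J22 <- (fy1[, 2] - fy0[, 2]) / (2 * h)
  detJ <- J11 * J22 - J12 * J21
  if (any(detJ <= 0))
    stop("warp folds on the image domain (non-positive Jacobian)")
  invisible(TRUE)
}
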