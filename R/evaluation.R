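# Registration assessment: SSIM, delineated-line coincidence rate,
# Canny-edge overlays and marker-position error statistics.

#' Structural similarity index (SSIM)
#'
#' Mean SSIM over the image with an 11 x 11 Gaussian window
#' (sigma 1.5) and the standard constants K1 = 0.01, K2 = 0.03 on the
#' [0, 1] intensity range.
#'
#' @param a,b \linkS4class{ThermalImage} objects or matrices of equal
#'   shape.
#' @return numeric in [-1, 1]; 1 iff the images are identical.
#' @export
ssimIndex <- function(a, b) {
  ma <- .as_pixels(a); mb <- .as_pixels(b)
  .check_same_shape(ma, mb)
  w <- .gauss_kernel(1.5, truncate = 10 / 3)  # 11 x 11
  C1 <- 0.01^2; C2 <- 0.03^2
  mua <- .filter2(ma, w); mub <- .filter2(mb, w)
  va <- .filter2(ma * ma, w) - mua^2
  vb <- .filter2(mb * mb, w) - mub^2
  cab <- .filter2(ma * mb, w) - mua * mub
  s <- ((2 * mua * mub + C1) * (2 * cab + C2)) /
    ((mua^2 + mub^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Coincidence rate of two delineated line masks
#'
#' Tolerant Jaccard overlap in percent:
#' 100 * |overlap| / |union| where the overlap counts pixels of either
#' mask lying within \code{tolPx} (Euclidean, via dilation with a disc)
#' of the other, and the union is the plain union of the two masks.
#' \code{tolPx = 0} gives the exact Jaccard index. Symmetric, and
#' monotone non-decreasing in \code{tolPx}.
#'
#' @param m1,m2 non-empty logical matrices of equal shape.
#' @param tolPx matching tolerance in px.
#' @return percent in [0, 100].
#' @export
coincidenceRate <- function(m1, m2, tolPx = 1) {
  .check_same_shape(m1, m2)
  stopifnot(any(m1), any(m2), tolPx >= 0)
  grow <- function(m) {
    if (tolPx == 0) return(m)
    EBImage::dilate(m * 1, EBImage::makeBrush(2 * ceiling(tolPx) + 1,
                                              "disc")) > 0
  }
  overlap <- (m1 & grow(m2)) | (m2 & grow(m1))
  100 * sum(overlap) / sum(m1 | m2)
}

#' Canny edge detection
#'
#' Gaussian smoothing, central-difference gradients, quantized-
#' direction non-maximal suppression and double-threshold hysteresis
#' (weak edges survive only in components containing a strong edge).
#' Thresholds are fractions of the maximum gradient magnitude.
#'
#' @param img a \linkS4class{ThermalImage} or matrix.
#' @param low,high hysteresis thresholds in (0, 1), low < high.
#' @param sigma smoothing scale, px.
#' @return logical edge matrix.
#' @export
cannyEdges <- function(img, low = 0.1, high = 0.2, sigma = 1.4) {
  stopifnot(low > 0, high > low, high < 1, sigma > 0)
  m <- EBImage::gblur(.as_pixels(img), sigma)
  g <- .gradients(m)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx <= 0) return(matrix(FALSE, nrow(m), ncol(m)))
  mag <- mag / mx
  ang <- atan2(g$gy, g$gx) %% pi
  # quantize into 4 directions: 0, 45, 90, 135 degrees
  q <- floor((ang + pi / 8) / (pi / 4)) %% 4
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mag
  sh <- function(dy, dx) pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  nms <- (q == 0 & mag >= sh(0, -1) & mag >= sh(0, 1)) |
    (q == 1 & mag >= sh(-1, 1) & mag >= sh(1, -1)) |
    (q == 2 & mag >= sh(-1, 0) & mag >= sh(1, 0)) |
    (q == 3 & mag >= sh(-1, -1) & mag >= sh(1, 1))
  nms <- nms & mag >= low
  strong <- nms & mag >= high
  if (!any(strong)) return(strong)
  lab <- .label8(nms)
  keep <- unique(lab[strong])
  nms & matrix(lab %in% keep, H, W)
}

#' Canny-edge overlay of a registered pair
#'
#' White = edges only in the (warped) source, red = edges only in the
#' target, green = edges present in both within 1 px.
#'
#' @param warpedSource,target \linkS4class{ThermalImage} objects or
#'   matrices of equal shape.
#' @param ... passed to \code{\link{cannyEdges}}.
#' @return H x W x 3 numeric array (RGB in [0, 1]).
#' @export
cannyOverlay <- function(warpedSource, target, ...) {
  es <- cannyEdges(warpedSource, ...)
  et <- cannyEdges(target, ...)
  .check_same_shape(es, et)
  near <- function(m) EBImage::dilate(m * 1, EBImage::makeBrush(3, "box")) > 0
  both <- (es & near(et)) | (et & near(es))
  white <- es & !both
  red <- et & !both
  out <- array(0, c(nrow(es), ncol(es), 3))
  out[, , 1] <- (white | red) * 1   # white (1,1,1), red (1,0,0)
  out[, , 2] <- (white | both) * 1  # green (0,1,0)
  out[, , 3] <- white * 1
  out
}

#' Marker-position error statistics
#'
#' Euclidean distance between corresponding rows of two point sets,
#' summarized as min / mean / max (px).
#'
#' @param pred n x 2 matrix of predicted (x, y).
#' @param truth n x 2 matrix of reference (x, y), matched by row.
#' @return named list: \code{min}, \code{mean}, \code{max}, \code{n}.
#' @export
markerError <- function(pred, truth) {
  pred <- rbind(pred); truth <- rbind(truth)
  stopifnot(nrow(pred) == nrow(truth), ncol(pred) == 2,
            ncol(truth) == 2, nrow(pred) >= 1)
  d <- sqrt(rowSums((pred - truth)^2))
  list(min = min(d), mean = mean(d), max = max(d), n = length(d))
}
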