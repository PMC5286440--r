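# Corner detection and adaptive non-maximal suppression.

#' Modified Harris corner detection
#'
#' Computes the Harris response \eqn{R = \det M - k\,\mathrm{tr}(M)^2}
#' from the Gaussian-windowed gradient autocorrelation matrix M and
#' returns the strict 8-neighborhood local maxima above
#' \code{relThreshold * max(R)}. A constant image yields an empty set.
#'
#' @param img a \linkS4class{ThermalImage} or numeric matrix in [0, 1].
#' @param sigma Gaussian window scale in px.
#' @param k trace weight; conventional range [0.04, 0.06].
#' @param relThreshold response threshold relative to the maximum, in
#'   (0, 1).
#' @return A \linkS4class{FeaturePointSet} of kind \code{"corner"}
#'   (suppression radii unset; run \code{\link{anms}}).
#' @examples
#' m <- matrix(0, 64, 64); m[20:44, 20:44] <- 1
#' harrisCorners(ThermalImage(m))
#' @export
harrisCorners <- function(img, sigma = 2, k = 0.04, relThreshold = 0.01) {
  stopifnot(sigma > 0, k >= 0.04 - 1e-12, k <= 0.06 + 1e-12,
            relThreshold > 0, relThreshold < 1)
  m <- .as_pixels(img)
  g <- .gradients(m)
  w <- .gauss_kernel(sigma)
  Ixx <- .filter2(g$gx * g$gx, w)
  Iyy <- .filter2(g$gy * g$gy, w)
  Ixy <- .filter2(g$gx * g$gy, w)
  R <- (Ixx * Iyy - Ixy^2) - k * (Ixx + Iyy)^2
  mx <- max(R)
  if (!is.finite(mx) || mx <= 0)
    return(FeaturePointSet(kind = character()))
  keep <- .local_maxima(R) & (R > relThreshold * mx)
  idx <- which(keep, arr.ind = TRUE)
  # quadratic subpixel interpolation of each response peak
  H <- nrow(R); W <- ncol(R)
  subpix <- function(rc) {
    r <- rc[1]; c <- rc[2]
    dx <- dy <- 0
    if (c > 1 && c < W) {
      den <- R[r, c - 1] - 2 * R[r, c] + R[r, c + 1]
      if (den < 0) dx <- max(-0.5, min(0.5, 0.5 * (R[r, c - 1] - R[r, c + 1]) / den))
    }
    if (r > 1 && r < H) {
      den <- R[r - 1, c] - 2 * R[r, c] + R[r + 1, c]
      if (den < 0) dy <- max(-0.5, min(0.5, 0.5 * (R[r - 1, c] - R[r + 1, c]) / den))
    }
    c(dx, dy)
  }
  off <- t(apply(idx, 1, subpix))
  FeaturePointSet(x = idx[, 2] - 1 + off[, 1], y = idx[, 1] - 1 + off[, 2],
                  response = R[keep], kind = "corner")
}

# suppression radii: distance to the nearest point whose scaled response
# dominates; the global maximum gets Inf
.anms_radii <- function(x, y, response, cRobust) {
  n <- length(x)
  r <- rep(Inf, n)
  if (n <= 1L) return(r)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  dominates <- outer(response, response * cRobust, "<") # [i, j]: c*resp_j > resp_i
  d2[!dominates] <- Inf
  diag(d2) <- Inf
  r <- sqrt(apply(d2, 1, min))
  r
}

#' Adaptive non-maximal suppression
#'
#' Assigns each point the suppression radius (distance to the nearest
#' point whose response, scaled by \code{cRobust}, exceeds its own; the
#' global maximum gets \code{Inf}) and keeps the \code{nTarget} points of
#' largest radius, giving a spatially spread, locally dominant subset.
#'
#' @param points a \linkS4class{FeaturePointSet}.
#' @param nTarget number of points to retain (all are returned, radii
#'   set, when \code{nTarget >= length(points)}).
#' @param cRobust robustness ratio in (0, 1]; 1 = plain dominance.
#' @return A \linkS4class{FeaturePointSet} with
#'   \code{suppressionRadius} filled, sorted by decreasing radius.
#' @export
anms <- function(points, nTarget, cRobust = 0.9) {
  stopifnot(is(points, "FeaturePointSet"), nTarget >= 1,
            cRobust > 0, cRobust <= 1)
  n <- length(points)
  if (n == 0L) return(points)
  r <- .anms_radii(points@x, points@y, points@response, cRobust)
  out <- points
  out@suppressionRadius <- r
  ord <- order(-r, -points@response, seq_len(n))
  out <- out[ord]
  out[seq_len(min(nTarget, n))]
}
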