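# Thin-plate-spline fitting, evaluation and image warping.
# Kernel U(r) = r^2 log(r^2) with U(0) = 0; the fitted map is
# f(x, y) = a1 + ax*x + ay*y + sum_j w_j U(|p - anchor_j|) per output
# coordinate, solved from L W = Y with L = [[K + lambda I, P], [P', 0]].

.tps_K <- function(a, b = a) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  K <- d2 * log(d2)
  K[d2 == 0] <- 0
  K
}

#' Fit a thin-plate spline from control pairs
#'
#' Solves the standard TPS linear system for the map taking each anchor
#' (input-side control point) to its target. With \code{lambda = 0} the
#' model interpolates exactly; positive \code{lambda} trades
#' interpolation for smoothness on noisy pairs.
#'
#' @param anchorPts n x 2 matrix of input-side points (n >= 4 after
#'   removal of duplicates).
#' @param targetPts n x 2 matrix of output-side points.
#' @param lambda regularization weight (>= 0) added to the kernel
#'   diagonal.
#' @return A \linkS4class{TPSModel}.
#' @examples
#' a <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
#' m <- fitTPS(a, a + 2)          # pure translation
#' tpsApply(m, c(5, 5))
#' @export
fitTPS <- function(anchorPts, targetPts, lambda = 0) {
  stopifnot(lambda >= 0)
  anchorPts <- rbind(anchorPts); targetPts <- rbind(targetPts)
  stopifnot(ncol(anchorPts) == 2, ncol(targetPts) == 2,
            nrow(anchorPts) == nrow(targetPts))
  key <- paste(anchorPts[, 1], anchorPts[, 2])
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      tgt <- targetPts[rows, , drop = FALSE]
      if (any(tgt[, 1] != tgt[1, 1]) || any(tgt[, 2] != tgt[1, 2]))
        stop("duplicate anchors with conflicting targets")
    }
    first <- !duplicated(key)
    anchorPts <- anchorPts[first, , drop = FALSE]
    targetPts <- targetPts[first, , drop = FALSE]
  }
  n <- nrow(anchorPts)
  if (n < 4L) stop("at least 4 distinct control points are required")
  K <- .tps_K(anchorPts) + lambda * diag(n)
  P <- cbind(1, anchorPts)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Y <- rbind(targetPts, matrix(0, 3, 2))
  Wmat <- tryCatch(solve(L, Y), error = function(e)
    stop("TPS system is singular (anchors collinear or degenerate): ",
         conditionMessage(e)))
  new("TPSModel", anchors = unname(anchorPts),
      coefX = unname(Wmat[, 1]), coefY = unname(Wmat[, 2]),
      lambda = lambda)
}

#' Apply a fitted TPS to points
#'
#' @param model a \linkS4class{TPSModel}.
#' @param p length-2 numeric (x, y) or an n x 2 matrix.
#' @return a point of the same shape as the input: length-2 vector or
#'   n x 2 matrix of transformed coordinates.
#' @export
tpsApply <- function(model, p) {
  stopifnot(is(model, "TPSModel"))
  vec <- is.null(dim(p))
  pts <- if (vec) matrix(as.numeric(p), 1, 2) else as.matrix(p)
  out <- cpp_tps_eval(model@anchors, model@coefX, model@coefY, pts)
  if (vec) c(out) else out
}

#' Bending energy of a fitted TPS
#'
#' \eqn{w^\top K w} summed over the two output coordinates;
#' nonnegative, and zero for purely affine maps.
#'
#' @param model a \linkS4class{TPSModel}.
#' @return numeric scalar.
#' @export
tpsBendingEnergy <- function(model) {
  n <- nrow(model@anchors)
  K <- .tps_K(model@anchors)
  wX <- model@coefX[seq_len(n)]
  wY <- model@coefY[seq_len(n)]
  drop(wX %*% K %*% wX + wY %*% K %*% wY)
}

#' Warp an image through a backward TPS map
#'
#' The model must be fitted as the backward map (output/target
#' coordinates to source coordinates) so each output pixel is sampled
#' from the source at \code{tpsApply(model, pixel)} by bilinear
#' interpolation; samples falling outside the source are 0.
#'
#' @param model a \linkS4class{TPSModel} (backward map).
#' @param source a \linkS4class{ThermalImage} or matrix.
#' @param outShape output c(height, width); defaults to the source
#'   shape.
#' @return A \linkS4class{ThermalImage}.
#' @export
warpImage <- function(model, source, outShape = NULL) {
  m <- .as_pixels(source)
  if (is.null(outShape)) outShape <- dim(m)
  out <- cpp_tps_warp(m, model@anchors, model@coefX, model@coefY,
                      as.integer(outShape[1]), as.integer(outShape[2]))
  ThermalImage(pmin(pmax(out, 0), 1),
               if (is(source, "ThermalImage")) bitDepth(source) else 8L)
}

#' Serialize a TPSModel to JSON
#'
#' @param model a \linkS4class{TPSModel}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
tpsToJson <- function(model, path) {
  jsonlite::write_json(
    list(anchors = model@anchors, coefX = model@coefX,
         coefY = model@coefY, lambda = model@lambda),
    path, digits = NA)
  invisible(path)
}

#' Read a TPSModel back from JSON
#'
#' @param path file written by \code{\link{tpsToJson}}.
#' @return A \linkS4class{TPSModel}.
#' @export
tpsFromJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TPSModel", anchors = matrix(o$anchors, ncol = 2),
      coefX = o$coefX, coefY = o$coefY, lambda = o$lambda)
}
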