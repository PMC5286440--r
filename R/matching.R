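# Two-tier correspondence: gradient-direction SAD relaxation matching,
# dual-map shape-context strict matching, per-side matching vectors and
# ANMS de-clustering of the merged control pairs.

#' GradientDescriptor: windowed gradient directions around a point
#'
#' @slot angles W x W matrix of gradient angles in [0, 2*pi).
#' @slot valid W x W logical matrix; FALSE where the gradient magnitude
#'   is zero (such pixels are excluded from SAD).
#' @slot center (x, y) of the described point.
#' @slot W window side in px (odd).
#' @export
setClass("GradientDescriptor",
  representation(angles = "matrix", valid = "matrix",
                 center = "numeric", W = "integer"))

setValidity("GradientDescriptor", function(object) {
  if (object@W %% 2L != 1L) return("window side must be odd")
  if (!identical(dim(object@angles), c(object@W, object@W)) ||
      !identical(dim(object@valid), c(object@W, object@W)))
    return("angle/valid windows must be W x W")
  TRUE
})

#' Gradient-direction descriptor of a feature point
#'
#' Central-difference gradient angles over a W x W window centered on
#' the (rounded) point. Zero-magnitude pixels carry angle 0 and are
#' flagged invalid. Points whose window leaves the image are not
#' describable and yield \code{NULL}.
#'
#' @param img a \linkS4class{ThermalImage} or matrix.
#' @param p length-2 numeric (x, y), 0-based.
#' @param W odd window side in px.
#' @return A \linkS4class{GradientDescriptor}, or \code{NULL} when the
#'   window violates the image border.
#' @export
gradientDescriptor <- function(img, p, W = 21) {
  stopifnot(W %% 2 == 1, W >= 1)
  m <- .as_pixels(img)
  x <- round(p[[1]]); y <- round(p[[2]])
  hw <- (W - 1) / 2
  if (x - hw < 0 || y - hw < 0 ||
      x + hw > ncol(m) - 1 || y + hw > nrow(m) - 1)
    return(NULL)
  g <- .gradients(m)
  rows <- (y - hw):(y + hw) + 1
  cols <- (x - hw):(x + hw) + 1
  gx <- g$gx[rows, cols, drop = FALSE]
  gy <- g$gy[rows, cols, drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  ang[mag <= 1e-12] <- 0
  new("GradientDescriptor", angles = ang, valid = mag > 1e-12,
      center = c(x, y), W = as.integer(W))
}

#' Circular SAD between two gradient descriptors
#'
#' Sum over pixels valid in both windows of the circular angular
#' difference \eqn{\min(|\Delta|, 2\pi - |\Delta|)}. Returns \code{Inf}
#' when no pixel is valid in both.
#'
#' @param dS,dT \linkS4class{GradientDescriptor} objects of equal W.
#' @return numeric cost (radians summed over valid pixels).
#' @export
sadScore <- function(dS, dT) {
  stopifnot(is(dS, "GradientDescriptor"), is(dT, "GradientDescriptor"))
  if (dS@W != dT@W) stop("descriptor window sizes differ")
  ok <- dS@valid & dT@valid
  if (!any(ok)) return(Inf)
  d <- abs(dS@angles[ok] - dT@angles[ok]) %% (2 * pi)
  sum(pmin(d, 2 * pi - d))
}

#' Relaxation matching by gradient-direction SAD template search
#'
#' For every describable source point, scans all candidate centers
#' within \code{searchRadius} of the same coordinates in the target
#' image and keeps the minimum-SAD location. Matches are permissive:
#' mutual consistency is not enforced, mismatches are expected and are
#' revised later by the matching vectors.
#'
#' @param srcPts a \linkS4class{FeaturePointSet} (source features).
#' @param srcImg,tgtImg \linkS4class{ThermalImage} objects of equal
#'   size.
#' @param W odd descriptor window side, px.
#' @param searchRadius search radius in the target, px.
#' @param ratioMax distinctiveness filter: keep a match only when its
#'   SAD is at most \code{ratioMax} times the best SAD found more than
#'   2 px away from the winner (1 disables the filter).
#' @return A \linkS4class{MatchSet} with provenance \code{"relaxed"};
#'   points too close to the border to describe are skipped.
#' @export
relaxationMatch <- function(srcPts, srcImg, tgtImg, W = 21,
                            searchRadius = 30, ratioMax = 0.9) {
  stopifnot(W %% 2 == 1, searchRadius >= 1, ratioMax > 0, ratioMax <= 1)
  ms <- .as_pixels(srcImg); mt <- .as_pixels(tgtImg)
  .check_same_shape(ms, mt)
  gs <- .gradients(ms); gt <- .gradients(mt)
  angS <- atan2(gs$gy, gs$gx) %% (2 * pi)
  angT <- atan2(gt$gy, gt$gx) %% (2 * pi)
  valS <- (gs$gx^2 + gs$gy^2) > 1e-24
  valT <- (gt$gx^2 + gt$gy^2) > 1e-24
  angS[!valS] <- 0; angT[!valT] <- 0
  hw <- (W - 1) / 2
  x <- round(srcPts@x); y <- round(srcPts@y)
  inb <- x - hw >= 0 & y - hw >= 0 &
    x + hw <= ncol(ms) - 1 & y + hw <= nrow(ms) - 1
  x <- x[inb]; y <- y[inb]
  if (length(x) == 0L)
    return(MatchSet(provenance = character()))
  storage.mode(valS) <- "integer"; storage.mode(valT) <- "integer"
  res <- cpp_relax_search(angS, valS, angT, valT,
                          as.integer(x), as.integer(y),
                          as.integer(W), as.integer(searchRadius))
  keep <- is.finite(res[, 3])
  if (ratioMax < 1)
    keep <- keep & (res[, 3] <= ratioMax * res[, 4])
  # carry subpixel source coordinates: the SAD displacement is measured
  # from the rounded position, so shift the target by the same fraction
  sx <- srcPts@x[inb]; sy <- srcPts@y[inb]
  tx <- sx + (res[, 1] - x)
  ty <- sy + (res[, 2] - y)
  # enforce one-to-one on the target side: keep the cheapest claimant
  ord <- order(res[keep, 3])
  kx <- sx[keep][ord]; ky <- sy[keep][ord]
  ktx <- tx[keep][ord]; kty <- ty[keep][ord]
  kc <- res[keep, 3][ord]
  first <- !duplicated(paste(round(ktx), round(kty)))
  MatchSet(xs = kx[first], ys = ky[first],
           xt = ktx[first], yt = kty[first],
           cost = kc[first], provenance = "relaxed")
}

#' ShapeContextDescriptor: dual-map log-polar histogram
#'
#' 12 angular x 5 radial bins over the vascular skeleton map
#' concatenated with the same binning over the binary heat-pattern map
#' (120 bins total); each 60-bin half is normalized to sum 1 (an
#' all-zero half stays all-zero).
#'
#' @slot bins numeric vector, length 2 * nAngle * nRad; skeleton half
#'   first. Within a half, index = angleBin * nRad + radialBin (0-based).
#' @slot nAngle,nRad bin counts.
#' @slot R outer radius in px.
#' @slot center (x, y) of the described point.
#' @export
setClass("ShapeContextDescriptor",
  representation(bins = "numeric", nAngle = "integer", nRad = "integer",
                 R = "numeric", center = "numeric"))

setValidity("ShapeContextDescriptor", function(object) {
  K <- object@nAngle * object@nRad
  if (length(object@bins) != 2L * K)
    return("bins must have length 2 * nAngle * nRad")
  if (any(object@bins < 0)) return("bins must be nonnegative")
  for (half in list(object@bins[1:K], object@bins[(K + 1):(2 * K)])) {
    s <- sum(half)
    if (s > 0 && abs(s - 1) > 1e-9)
      return("each nonempty half must sum to 1")
  }
  TRUE
})

# log-polar bin index (0-based) for offsets dx, dy; NA outside [R/16, R)
.sc_bin <- function(dx, dy, R, nAngle, nRad) {
  r <- sqrt(dx^2 + dy^2)
  ok <- r >= R / 16 & r < R
  theta <- atan2(dy, dx) %% (2 * pi)
  ai <- pmin(floor(theta / (2 * pi / nAngle)), nAngle - 1)
  ri <- pmin(floor(nRad * log(r / (R / 16)) / log(16)), nRad - 1)
  ifelse(ok, ai * nRad + ri, NA_real_)
}

#' Dual-map shape-context descriptor of a point
#'
#' Counts the set pixels of the skeleton map and of the heat-pattern
#' map falling in each log-polar bin centered at \code{p}: angular bins
#' of width 2*pi/nAngle starting at angle 0 = +x axis, radial edges
#' log-uniform from R/16 to R (pixels nearer than R/16 or at R and
#' beyond are outside the descriptor support). The two 60-bin halves
#' are normalized independently.
#'
#' @param p length-2 numeric (x, y), 0-based.
#' @param skel logical skeleton matrix.
#' @param heatMask logical heat-pattern matrix of the same size.
#' @param R outer radius, px.
#' @param nAngle,nRad angular and radial bin counts.
#' @return A \linkS4class{ShapeContextDescriptor}.
#' @export
shapeContext <- function(p, skel, heatMask, R = 100, nAngle = 12L,
                         nRad = 5L) {
  stopifnot(R > 0)
  .check_same_shape(skel, heatMask)
  K <- nAngle * nRad
  half <- function(mask) {
    out <- numeric(K)
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx)) {
      dx <- idx[, 2] - 1 - p[[1]]
      dy <- idx[, 1] - 1 - p[[2]]
      b <- .sc_bin(dx, dy, R, nAngle, nRad)
      b <- b[!is.na(b) & !(dx == 0 & dy == 0)]
      if (length(b)) {
        cnt <- tabulate(b + 1, K)
        out <- cnt / sum(cnt)
      }
    }
    out
  }
  new("ShapeContextDescriptor",
      bins = c(half(skel), half(heatMask)),
      nAngle = as.integer(nAngle), nRad = as.integer(nRad), R = R,
      center = c(p[[1]], p[[2]]))
}

#' Chi-squared shape-context matching cost
#'
#' \eqn{C_s = \frac12 \sum_k (g_k - h_k)^2 / (g_k + h_k)}, terms with
#' zero denominator contributing 0. Symmetric; bounded by 2 for the
#' two-half normalized descriptors.
#'
#' @param g,h \linkS4class{ShapeContextDescriptor} objects with equal
#'   bin counts, or plain numeric histogram vectors.
#' @return numeric cost.
#' @export
scCost <- function(g, h) {
  gv <- if (is(g, "ShapeContextDescriptor")) g@bins else as.numeric(g)
  hv <- if (is(h, "ShapeContextDescriptor")) h@bins else as.numeric(h)
  if (length(gv) != length(hv)) stop("bin counts differ")
  den <- gv + hv
  ok <- den > 0
  0.5 * sum((gv[ok] - hv[ok])^2 / den[ok])
}

#' Optimal one-to-one assignment of a cost matrix
#'
#' Minimum-total-cost assignment (Hungarian / shortest augmenting path
#' with potentials, O(n^3)); assigns every row when rows <= cols,
#' otherwise every column. Equals the exhaustive permutation minimum.
#'
#' @param cost numeric cost matrix (finite entries).
#' @return list: \code{assignment} (for each row, the assigned column
#'   index or \code{NA}), \code{cost} (total assigned cost).
#' @export
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr > nc) {
    sol <- solveAssignment(t(cost))
    assignment <- rep(NA_integer_, nr)
    assignment[sol$assignment] <- seq_len(nc)
    return(list(assignment = assignment, cost = sol$cost))
  }
  n <- nr; m <- nc
  # potentials u, v; p[j] = row matched to column j (0 = free);
  # column index m + 1 plays the role of the virtual start column
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- logical(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- cost[i0, ] - u[i0] - v[seq_len(m)]
      upd <- !used[seq_len(m)] & cur < minv
      minv[upd] <- cur[upd]
      way[seq_len(m)][upd] <- j0
      free <- which(!used[seq_len(m)])
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedCols <- which(used)
      u[p[usedCols]] <- u[p[usedCols]] + delta
      v[usedCols] <- v[usedCols] - delta
      minv[!used[seq_len(m)]] <- minv[!used[seq_len(m)]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assignment <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0L) assignment[p[j]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

#' Strict matching on a shape-context cost matrix
#'
#' Computes the optimal one-to-one assignment of the cost matrix, then
#' keeps a pair (i, j) only if it is both the row and the column
#' minimum and passes the dual second-best ratio tests
#' \eqn{C(i,j)/C(i_{sec},j) \le T} and \eqn{C(i,j)/C(i,j_{sec}) \le T}
#' (a zero optimal cost always passes). The survivors are few but
#' stable.
#'
#' @param cost numeric cost matrix.
#' @param T ratio threshold in (0, 1).
#' @return list: \code{pairs} (k x 2 matrix of kept row/col indices),
#'   \code{assignment}, \code{cost} as in
#'   \code{\link{solveAssignment}}.
#' @export
strictMatchCosts <- function(cost, T) {
  stopifnot(T > 0, T < 1)
  cost <- as.matrix(cost)
  sol <- solveAssignment(cost)
  keep <- matrix(integer(), 0, 2)
  for (i in which(!is.na(sol$assignment))) {
    j <- sol$assignment[i]
    cij <- cost[i, j]
    if (cij > min(cost[i, ]) || cij > min(cost[, j])) next
    rowRest <- cost[i, -j]
    colRest <- cost[-i, j]
    iSec <- if (length(colRest)) min(colRest) else Inf
    jSec <- if (length(rowRest)) min(rowRest) else Inf
    r1 <- if (cij == 0) 0 else cij / iSec
    r2 <- if (cij == 0) 0 else cij / jSec
    if (r1 <= T && r2 <= T) keep <- rbind(keep, c(i, j))
  }
  list(pairs = keep, assignment = sol$assignment, cost = sol$cost)
}

#' Strict shape-context matching of two feature sets
#'
#' Builds descriptors for both feature sets on their own skeleton and
#' heat-pattern maps, forms the chi-squared cost matrix and applies
#' \code{\link{strictMatchCosts}}. The ratio threshold is
#' \eqn{T = (R - r_s) / R} with \eqn{r_s} the median finite ANMS
#' suppression radius of the source set, clamped into (0, 1).
#'
#' @param srcPts,tgtPts \linkS4class{FeaturePointSet} objects.
#' @param srcMaps,tgtMaps lists with \code{skeleton} and
#'   \code{heatMask} matrices (as from \code{\link{detectFeatures}}).
#' @param R shape-context radius, px.
#' @param nAngle,nRad bin counts.
#' @param T ratio threshold; computed from the suppression radii when
#'   \code{NULL}.
#' @return A \linkS4class{MatchSet} with provenance \code{"strict"}.
#' @export
strictMatch <- function(srcPts, tgtPts, srcMaps, tgtMaps, R = 100,
                        nAngle = 12L, nRad = 5L, T = NULL) {
  if (length(srcPts) == 0L || length(tgtPts) == 0L)
    return(MatchSet(provenance = character()))
  if (is.null(T)) {
    rs <- suppressionRadius(srcPts)
    rs <- rs[is.finite(rs)]
    T <- if (length(rs)) (R - stats::median(rs)) / R else 0.8
    T <- min(max(T, 1e-3), 1 - 1e-3)
  }
  dS <- lapply(seq_len(length(srcPts)), function(i)
    shapeContext(coords(srcPts)[i, ], srcMaps$skeleton, srcMaps$heatMask,
                 R, nAngle, nRad)@bins)
  dT <- lapply(seq_len(length(tgtPts)), function(i)
    shapeContext(coords(tgtPts)[i, ], tgtMaps$skeleton, tgtMaps$heatMask,
                 R, nAngle, nRad)@bins)
  gS <- do.call(rbind, dS)
  gT <- do.call(rbind, dT)
  cost <- matrix(0, nrow(gS), nrow(gT))
  for (i in seq_len(nrow(gS))) {
    gi <- gS[i, ]
    num <- sweep(gT, 2, gi, "-")^2
    den <- sweep(gT, 2, gi, "+")
    num[den == 0] <- 0
    den[den == 0] <- 1
    cost[i, ] <- 0.5 * rowSums(num / den)
  }
  res <- strictMatchCosts(cost, T)
  if (nrow(res$pairs) == 0L)
    return(MatchSet(provenance = character()))
  cs <- coords(srcPts)[res$pairs[, 1], , drop = FALSE]
  ct <- coords(tgtPts)[res$pairs[, 2], , drop = FALSE]
  MatchSet(xs = cs[, 1], ys = cs[, 2], xt = ct[, 1], yt = ct[, 2],
           cost = cost[res$pairs], provenance = "strict")
}

#' Train per-side matching vectors from strict matches
#'
#' Splits the strict matches at \code{midlineX} (source x < midline =
#' left) and takes the component-wise median displacement of each side
#' as that side's matching vector. A side without strict support gets
#' \code{NULL} and downstream revision keeps nothing there.
#'
#' @param strict a \linkS4class{MatchSet} (strict tier).
#' @param midlineX dividing x coordinate, px.
#' @return list with elements \code{left} and \code{right}; each is
#'   \code{NULL} or a list \code{(displacement = c(dx, dy), support)}.
#' @export
trainMatchingVectors <- function(strict, midlineX) {
  dx <- strict@xt - strict@xs
  dy <- strict@yt - strict@ys
  side <- ifelse(strict@xs < midlineX, "left", "right")
  mk <- function(s) {
    sel <- side == s
    if (!any(sel)) return(NULL)
    list(displacement = c(stats::median(dx[sel]), stats::median(dy[sel])),
         support = sum(sel))
  }
  list(left = mk("left"), right = mk("right"), midlineX = midlineX)
}

#' Revise relaxed matches by the matching vectors
#'
#' Keeps a relaxed match iff the matching vector of its side exists and
#' the Euclidean distance between its displacement and the vector is at
#' most \code{tolPx}.
#'
#' @param relaxed a \linkS4class{MatchSet} (relaxed tier).
#' @param vectors list from \code{\link{trainMatchingVectors}}.
#' @param tolPx tolerance in px.
#' @return A \linkS4class{MatchSet} with provenance
#'   \code{"relaxed_revised"}.
#' @export
reviseRelaxed <- function(relaxed, vectors, tolPx = 10) {
  stopifnot(tolPx > 0)
  if (length(relaxed) == 0L) return(MatchSet(provenance = character()))
  dx <- relaxed@xt - relaxed@xs
  dy <- relaxed@yt - relaxed@ys
  left <- relaxed@xs < vectors$midlineX
  keep <- logical(length(relaxed))
  for (s in c("left", "right")) {
    v <- vectors[[s]]
    sel <- if (s == "left") left else !left
    if (is.null(v)) next
    dev <- sqrt((dx - v$displacement[1])^2 + (dy - v$displacement[2])^2)
    keep[sel] <- dev[sel] <= tolPx
  }
  out <- relaxed[keep]
  out@provenance <- rep("relaxed_revised", length(out))
  out
}

#' Merge strict and revised matches into spread control pairs
#'
#' Takes the union of the strict and revised-relaxed tiers (the strict
#' pair wins when both tiers claim the same source point), then runs
#' ANMS over the source points with response = -cost so the retained
#' pairs are spatially spread and locally cheapest.
#'
#' @param strict,relaxedRevised \linkS4class{MatchSet} tiers.
#' @param anmsN maximum number of control pairs to keep.
#' @param cRobust ANMS robustness ratio.
#' @return A \linkS4class{MatchSet}: the control-point pairs.
#' @export
mergeControlPairs <- function(strict, relaxedRevised, anmsN = 40,
                              cRobust = 0.9) {
  skey <- paste(strict@xs, strict@ys)
  rkey <- paste(relaxedRevised@xs, relaxedRevised@ys)
  rr <- relaxedRevised[!(rkey %in% skey)]
  all <- new("MatchSet",
             xs = c(strict@xs, rr@xs), ys = c(strict@ys, rr@ys),
             xt = c(strict@xt, rr@xt), yt = c(strict@yt, rr@yt),
             cost = c(strict@cost, rr@cost),
             provenance = c(strict@provenance, rr@provenance))
  # drop duplicate target claims across tiers (strict listed first wins)
  tkey <- paste(all@xt, all@yt)
  all <- all[!duplicated(tkey)]
  if (length(all) < 4L)
    stop(structure(class = c("thermoregUnderdetermined", "error",
                             "condition"),
                   list(message = sprintf(
                     "control-pair merge left %d pair(s); at least 4 are needed for TPS",
                     length(all)), call = sys.call())))
  r <- .anms_radii(all@xs, all@ys, -all@cost, cRobust)
  ord <- order(-r, all@cost, seq_along(r))
  keep <- sort(ord[seq_len(min(anmsN, length(all)))])
  out <- all[keep]
  if (length(out) < 4L)
    stop(structure(class = c("thermoregUnderdetermined", "error",
                             "condition"),
                   list(message = "fewer than 4 control pairs after ANMS",
                        call = sys.call())))
  out
}
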