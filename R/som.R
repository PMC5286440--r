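# Competitive winner-guided control-point refinement: candidate
# positions on a lattice around each target-side control point are
# scored by the mutual information of the resulting registration; the
# winner pulls its control point (and, with a Gaussian neighborhood
# kernel, the others) toward it under decaying SOM schedules.

#' Mutual information of two images
#'
#' MI (in nats) from the joint histogram of intensities clamped to
#' [0, 1]. \code{MI(a, a)} equals the histogram entropy of \code{a}.
#'
#' @param a,b \linkS4class{ThermalImage} objects or matrices of equal
#'   shape.
#' @param bins joint-histogram bins per axis (>= 2).
#' @return numeric, nats.
#' @export
mutualInformation <- function(a, b, bins = 32L) {
  stopifnot(bins >= 2)
  ma <- .as_pixels(a); mb <- .as_pixels(b)
  .check_same_shape(ma, mb)
  if (length(ma) == 0L) stop("empty image overlap")
  cpp_mi(ma, mb, as.integer(bins))
}

#' Competition units around a point
#'
#' A G x G lattice centered at \code{p} with spacing \code{s}, clipped
#' to the image bounds (units falling outside are dropped; the center
#' unit, \code{p} itself, is always retained). Units are ordered
#' row-major by lattice position, which fixes the deterministic
#' tie-break order.
#'
#' @param p length-2 numeric (x, y).
#' @param G odd lattice side.
#' @param s lattice spacing, px.
#' @param width,height image bounds, px.
#' @return list: \code{units} (k x 2 matrix), \code{centerIdx} (row of
#'   the center unit).
#' @export
competitionUnits <- function(p, G, s, width, height) {
  stopifnot(G %% 2 == 1, G >= 1, s >= 1)
  h <- (G - 1) / 2
  off <- (-h:h) * s
  grid <- cbind(x = rep(p[[1]] + off, times = G),
                y = rep(p[[2]] + off, each = G))
  inb <- grid[, 1] >= 0 & grid[, 1] <= width - 1 &
    grid[, 2] >= 0 & grid[, 2] <= height - 1
  isCenter <- grid[, 1] == p[[1]] & grid[, 2] == p[[2]]
  inb <- inb | isCenter   # center retained even at the image corner
  units <- grid[inb, , drop = FALSE]
  list(units = units, centerIdx = which(isCenter[inb])[1])
}

# backward-fit TPS for a candidate target-side configuration and its
# registration MI; NULL when the fit fails
.candidate_mi <- function(srcM, tgtM, tgtSide, srcSide, lambda, bins,
                          stride = 1L) {
  model <- tryCatch(fitTPS(tgtSide, srcSide, lambda),
                    error = function(e) NULL)
  if (is.null(model)) return(NULL)
  cpp_tps_warp_mi(srcM, tgtM, model@anchors, model@coefX, model@coefY,
                  as.integer(bins), as.integer(stride))
}

#' Winner search for one control point
#'
#' Replaces the target-side point \code{idx} by each competition unit
#' in turn, refits the backward TPS, warps the source and scores the
#' registration by mutual information. The winner is the unit of
#' maximum MI; ties break toward the unit nearest the current position,
#' then the lowest lattice index. Units whose TPS fit fails are
#' skipped.
#'
#' @param pairs a \linkS4class{MatchSet} of control pairs.
#' @param idx index of the pair under adjustment.
#' @param units list from \code{\link{competitionUnits}}.
#' @param source,target \linkS4class{ThermalImage} objects.
#' @param miBins MI histogram bins.
#' @param lambda TPS regularization.
#' @param miTol noise margin in nats: off-center units win only when
#'   they beat the center unit's MI by more than this.
#' @param miStride stride of the MI scoring grid.
#' @return list: \code{point} (winner x, y), \code{mi}, \code{unitIdx}.
#' @export
findWinner <- function(pairs, idx, units, source, target, miBins = 32L,
                       lambda = 0, miTol = 0, miStride = 1L) {
  stopifnot(idx >= 1, idx <= length(pairs))
  srcM <- .as_pixels(source); tgtM <- .as_pixels(target)
  tgtSide <- targetPoints(pairs)
  srcSide <- sourcePoints(pairs)
  cur <- tgtSide[idx, ]
  u <- units$units
  mis <- rep(NA_real_, nrow(u))
  for (k in seq_len(nrow(u))) {
    cand <- tgtSide
    cand[idx, ] <- u[k, ]
    mis[k] <- .candidate_mi(srcM, tgtM, cand, srcSide, lambda,
                            miBins, miStride) %||% NA_real_
  }
  if (all(is.na(mis))) stop("no viable competition unit (all TPS fits failed)")
  ctr <- units$centerIdx
  best <- max(mis, na.rm = TRUE)
  if (!is.na(mis[ctr]) && best <= mis[ctr] + miTol)
    return(list(point = u[ctr, ], mi = mis[ctr], unitIdx = ctr))
  cand <- which(!is.na(mis) & mis >= best - 1e-12)
  if (length(cand) > 1L) {
    d2 <- (u[cand, 1] - cur[1])^2 + (u[cand, 2] - cur[2])^2
    cand <- cand[d2 == min(d2)]
    cand <- cand[1]   # lowest lattice index among remaining ties
  }
  list(point = u[cand, ], mi = mis[cand], unitIdx = cand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SOMState: the refinement state across iterations
#'
#' @slot pairs current control pairs.
#' @slot origins original target-side positions (trust-region anchors).
#' @slot iter completed iteration count.
#' @slot miTrace committed MI after each iteration (index 1 = initial).
#' @slot bestPairs best committed configuration so far.
#' @slot bestMI its MI.
#' @slot centerRun consecutive iterations with every winner at its
#'   center.
#' @slot converged stability reached.
#' @export
setClass("SOMState",
  representation(pairs = "MatchSet", origins = "matrix",
                 iter = "integer", miTrace = "numeric",
                 bestPairs = "MatchSet", bestMI = "numeric",
                 centerRun = "integer", converged = "logical"))

setValidity("SOMState", function(object) {
  if (length(object@miTrace) && !all(is.finite(object@miTrace)))
    return("MI trace entries must be finite")
  if (length(object@miTrace) > 1 &&
      any(diff(object@miTrace) < -1e-9))
    return("committed MI must be non-decreasing")
  TRUE
})

setMethod("show", "SOMState", function(object) {
  cat(sprintf("SOMState: iteration %d, committed MI %.4f nats (%s)\n",
              object@iter, object@bestMI,
              if (object@converged) "converged" else "running"))
})

# initial state for a control-pair configuration
.som_init <- function(pairs, source, target, params, lambda = 0) {
  mi0 <- .candidate_mi(.as_pixels(source), .as_pixels(target),
                       targetPoints(pairs), sourcePoints(pairs),
                       lambda, params@miBins)
  if (is.null(mi0)) stop("initial TPS fit failed for SOM refinement")
  new("SOMState", pairs = pairs, origins = targetPoints(pairs),
      iter = 0L, miTrace = mi0, bestPairs = pairs, bestMI = mi0,
      centerRun = 0L, converged = FALSE)
}

#' One SOM iteration (sweep over all control points)
#'
#' For each control point in sequence: find the winner unit
#' \eqn{N_p}; move the point toward it by the learning rate
#' \eqn{EtaN(i) = \eta_0 (1 - i/i_{max})}; move every other control
#' point by the same offset scaled by the neighborhood kernel
#' \eqn{K(i) = EtaN(i) \exp(-d(N, N_p)^2 / (2\,SigN(i)^2))} with
#' \eqn{SigN(i) = Sig_0 (1 - i/i_{max})} and d the Euclidean distance
#' between control points. The sweep is committed only if the global
#' registration MI did not decrease; otherwise it is reverted and the
#' iteration is a null move.
#'
#' @param state a \linkS4class{SOMState}.
#' @param params a \linkS4class{SOMParams}.
#' @param source,target \linkS4class{ThermalImage} objects.
#' @param lambda TPS regularization used in refits.
#' @return the updated \linkS4class{SOMState}.
#' @export
somStep <- function(state, params, source, target, lambda = 0) {
  stopifnot(!state@converged, state@iter < params@iMax)
  srcM <- .as_pixels(source); tgtM <- .as_pixels(target)
  H <- nrow(tgtM); W <- ncol(tgtM)
  i <- state@iter
  eta <- params@eta0 * (1 - i / params@iMax)
  sig <- max(params@sig0 * (1 - i / params@iMax), 1e-6)
  pairs <- state@pairs
  tp <- targetPoints(pairs)
  allCenters <- TRUE
  for (j in seq_len(nrow(tp))) {
    pairs@xt <- tp[, 1]; pairs@yt <- tp[, 2]
    units <- competitionUnits(tp[j, ], params@gridSize,
                              params@gridSpacing, W, H)
    if (is.finite(params@trustRadius)) {
      d0 <- sqrt((units$units[, 1] - state@origins[j, 1])^2 +
                   (units$units[, 2] - state@origins[j, 2])^2)
      ok <- d0 <= params@trustRadius
      ok[units$centerIdx] <- TRUE   # the current position always stays
      units$units <- units$units[ok, , drop = FALSE]
      units$centerIdx <- sum(ok[seq_len(units$centerIdx)])
    }
    w <- findWinner(pairs, j, units, source, target, params@miBins,
                    lambda, miTol = params@miTol,
                    miStride = params@miStride)
    delta <- w$point - tp[j, ]
    if (any(delta != 0)) allCenters <- FALSE else next
    d2 <- (tp[, 1] - tp[j, 1])^2 + (tp[, 2] - tp[j, 2])^2
    Kk <- eta * exp(-d2 / (2 * sig^2))  # equals eta at the point itself
    tp <- tp + outer(Kk, delta)
    if (is.finite(params@trustRadius)) {
      off <- tp - state@origins
      dn <- sqrt(rowSums(off^2))
      over <- which(dn > params@trustRadius)
      if (length(over))
        tp[over, ] <- state@origins[over, , drop = FALSE] +
          off[over, , drop = FALSE] * (params@trustRadius / dn[over])
    }
    tp[, 1] <- pmin(pmax(tp[, 1], 0), W - 1)
    tp[, 2] <- pmin(pmax(tp[, 2], 0), H - 1)
  }
  pairs@xt <- tp[, 1]; pairs@yt <- tp[, 2]
  miNew <- .candidate_mi(srcM, tgtM, tp, sourcePoints(pairs), lambda,
                         params@miBins)
  committed <- !is.null(miNew) && miNew >= utils::tail(state@miTrace, 1)
  out <- state
  out@iter <- state@iter + 1L
  if (committed) {
    out@pairs <- pairs
    out@miTrace <- c(state@miTrace, miNew)
    if (miNew >= state@bestMI) {
      out@bestMI <- miNew
      out@bestPairs <- pairs
    }
  } else {
    out@miTrace <- c(state@miTrace, utils::tail(state@miTrace, 1))
  }
  out@centerRun <- if (allCenters) state@centerRun + 1L else 0L
  if (out@centerRun >= params@stabilityWindow) out@converged <- TRUE
  out
}

#' Refine control pairs by winner-guided SOM iterations
#'
#' Iterates \code{\link{somStep}} until every winner stays at its
#' center for \code{stabilityWindow} consecutive iterations, or the
#' iteration budget is exhausted, and returns the best-MI committed
#' configuration.
#'
#' @param pairs a \linkS4class{MatchSet} with >= 4 pairs.
#' @param source,target \linkS4class{ThermalImage} objects.
#' @param params a \linkS4class{SOMParams}.
#' @param lambda TPS regularization used in refits.
#' @return the final \linkS4class{SOMState}; the refined pairs are in
#'   slot \code{bestPairs}, the committed MI per iteration in
#'   \code{miTrace}.
#' @export
somRefine <- function(pairs, source, target, params = somParams(),
                      lambda = 0) {
  stopifnot(length(pairs) >= 4L)
  state <- .som_init(pairs, source, target, params, lambda)
  while (!state@converged && state@iter < params@iMax)
    state <- somStep(state, params, source, target, lambda)
  state
}
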