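# End-to-end registration pipeline:
# detect -> relax-match -> strict-match -> vector-revise -> merge/ANMS
# -> TPS -> SOM refine -> final TPS warp.

# union of forward and inverted backward relaxed tiers, one-to-one on
# both sides (cheapest claimant wins)
.merge_relaxed <- function(fwd, bwd) {
  xs <- c(fwd@xs, bwd@xt); ys <- c(fwd@ys, bwd@yt)
  xt <- c(fwd@xt, bwd@xs); yt <- c(fwd@yt, bwd@ys)
  cost <- c(fwd@cost, bwd@cost)
  ord <- order(cost)
  xs <- xs[ord]; ys <- ys[ord]; xt <- xt[ord]; yt <- yt[ord]
  cost <- cost[ord]
  keep <- !duplicated(paste(round(xs, 1), round(ys, 1))) &
    !duplicated(paste(round(xt, 1), round(yt, 1)))
  MatchSet(xs = xs[keep], ys = ys[keep], xt = xt[keep], yt = yt[keep],
           cost = cost[keep], provenance = "relaxed")
}

#' Register a longitudinal infrared image pair
#'
#' Runs the full marker-free pipeline on a source (earlier) and target
#' (later) frame: feature detection on both images (corners with ANMS
#' plus vascular-skeleton intersections), gradient-direction SAD
#' relaxation matching, dual-map shape-context strict matching,
#' matching-vector revision of the relaxed tier, control-pair merging
#' with ANMS, thin-plate-spline fitting, winner-guided SOM refinement
#' of the target-side control points by mutual-information
#' maximization, and the final backward-TPS warp of the source into
#' target geometry. Deterministic for fixed inputs and config.
#'
#' @param source,target \linkS4class{ThermalImage} objects of equal
#'   size, at least 32 x 32 px.
#' @param config a \linkS4class{PipelineConfig}.
#' @param refine logical; run the SOM refinement stage (default TRUE).
#' @param verbose print per-stage survivor counts.
#' @return A \linkS4class{RegistrationResult}.
#' @export
runRegistration <- function(source, target, config = pipelineConfig(),
                            refine = TRUE, verbose = FALSE) {
  stopifnot(is(source, "ThermalImage"), is(target, "ThermalImage"),
            is(config, "PipelineConfig"))
  ms <- pixels(source); mt <- pixels(target)
  if (nrow(ms) < 32 || ncol(ms) < 32)
    stop("images must be at least 32 x 32 px")
  .check_same_shape(ms, mt)
  if (isTRUE(config[["enhance_contrast"]])) {
    stretch <- function(m) {
      rg <- range(m)
      if (diff(rg) > 0) (m - rg[1]) / diff(rg) else m
    }
    source <- ThermalImage(stretch(ms), bitDepth(source))
    target <- ThermalImage(stretch(mt), bitDepth(target))
  }

  log <- list()
  note <- function(stage, n) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, count = n)
    if (verbose) message(sprintf("[thermoreg] %-24s %d", stage, n))
  }

  detS <- detectFeatures(source, config)
  detT <- detectFeatures(target, config)
  note("features_source", length(detS$points))
  note("features_target", length(detT$points))
  if (length(detS$points) == 0L || length(detT$points) == 0L)
    stop("no features detected (",
         if (length(detS$points) == 0L) "source" else "target",
         " image); pipeline starved at feature detection")

  # symmetric relaxation matching: source features searched in the
  # target, and target features searched in the source (inverted), so
  # control coverage does not depend on one frame's detections alone
  relaxedF <- relaxationMatch(detS$points, source, target,
                              W = config[["relax_window"]],
                              searchRadius = config[["relax_search_radius"]],
                              ratioMax = config[["relax_ratio_max"]])
  relaxedB <- relaxationMatch(detT$points, target, source,
                              W = config[["relax_window"]],
                              searchRadius = config[["relax_search_radius"]],
                              ratioMax = config[["relax_ratio_max"]])
  relaxed <- .merge_relaxed(relaxedF, relaxedB)
  note("relaxed_matches", length(relaxed))

  strict <- strictMatch(detS$points, detT$points,
                        srcMaps = detS, tgtMaps = detT,
                        R = config[["sc_radius"]],
                        nAngle = config[["sc_n_angle"]],
                        nRad = config[["sc_n_rad"]])
  note("strict_matches", length(strict))
  if (length(strict) == 0L)
    stop("no strict matches survived the ratio tests; ",
         "pipeline starved at strict matching")

  vectors <- trainMatchingVectors(strict, midlineX = ncol(ms) / 2)
  revised <- reviseRelaxed(relaxed, vectors,
                           tolPx = config[["vector_tol"]])
  note("relaxed_revised", length(revised))

  pairs <- mergeControlPairs(strict, revised,
                             anmsN = config[["pair_anms_n"]],
                             cRobust = config[["anms_c_robust"]])
  note("control_pairs", length(pairs))

  lam <- config[["tps_lambda"]]
  miBefore <- mutualInformation(source, target, config[["mi_bins"]])
  ssimBefore <- ssimIndex(source, target)

  trace <- numeric()
  converged <- TRUE
  if (refine) {
    params <- somParams(gridSize = config[["som_grid_size"]],
                        gridSpacing = config[["som_grid_spacing"]],
                        eta0 = config[["som_eta0"]],
                        sig0 = config[["som_sig0"]],
                        iMax = config[["som_i_max"]],
                        miBins = config[["mi_bins"]],
                        miTol = config[["som_mi_tol"]],
                        miStride = config[["som_mi_stride"]],
                        trustRadius = config[["som_trust_radius"]])
    state <- somRefine(pairs, source, target, params, lambda = lam)
    pairs <- state@bestPairs
    trace <- state@miTrace
    converged <- state@converged
    note("som_iterations", state@iter)
  }

  backward <- fitTPS(targetPoints(pairs), sourcePoints(pairs), lam)
  forward <- fitTPS(sourcePoints(pairs), targetPoints(pairs), lam)
  warped <- warpImage(backward, source, dim(mt))
  metrics <- list(ssim_before = ssimBefore,
                  ssim_after = ssimIndex(warped, target),
                  mi_before = miBefore,
                  mi_after = mutualInformation(warped, target,
                                               config[["mi_bins"]]))
  new("RegistrationResult", warpedSource = warped, controlPairs = pairs,
      forwardModel = forward, backwardModel = backward,
      metrics = metrics, somTrace = trace, converged = converged,
      stageLog = do.call(rbind, log))
}
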