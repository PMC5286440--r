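# Fixtures here use ground-truth landmark pairs as control points so the
# refinement's geometric behavior is measurable exactly.

truth_pairs <- function(pr, n = 12) {
  lm <- pr$landmarks
  idx <- round(seq(1, nrow(lm$source), length.out = min(n, nrow(lm$source))))
  MatchSet(lm$source[idx, 1], lm$source[idx, 2],
           lm$target[idx, 1], lm$target[idx, 2],
           cost = rep(0.1, length(idx)), provenance = "strict")
}

test_that("competition units form a clipped lattice around the point", {
  u <- competitionUnits(c(10, 10), 3, 2, 64, 64)
  expect_equal(nrow(u$units), 9)
  expect_setequal(u$units[, 1], c(8, 10, 12))
  expect_equal(u$units[u$centerIdx, ], c(x = 10, y = 10))

  corner <- competitionUnits(c(0, 0), 3, 2, 64, 64)
  expect_lt(nrow(corner$units), 9)
  expect_equal(corner$units[corner$centerIdx, ], c(x = 0, y = 0))
  expect_true(all(corner$units >= 0))

  expect_equal(nrow(competitionUnits(c(5, 5), 1, 2, 64, 64)$units), 1)
})

test_that("the winner stays at the center for a registered pair", {
  sc <- generateScene(11, noiseSigma = 0, intensityOffset = 0)
  pr <- renderPair(sc, identityWarp(), noiseSeeds = c(1L, 1L))
  pairs <- truth_pairs(pr)
  u <- competitionUnits(targetPoints(pairs)[2, ], 5, 2,
                        sc@width, sc@height)
  w <- findWinner(pairs, 2, u, pr$source, pr$target, miTol = 0.02,
                  miStride = 2L)
  expect_equal(unname(w$point), unname(targetPoints(pairs)[2, ]))
})

test_that("the winner corrects a one-lattice-step displacement", {
  # at a single lattice step the MI differences between the correcting
  # unit and its immediate neighbors sit at the histogram noise level,
  # so the check is recovery to within one lattice spacing
  hits <- 0
  for (s in 0:9) {
    sc <- generateScene(s)
    w0 <- randomSmoothWarp(100 + s, maxDisplacement = 10)
    pr <- renderPair(sc, w0)
    pairs <- truth_pairs(pr)
    truth <- targetPoints(pairs)[2, ]
    pairs@xt[2] <- pairs@xt[2] + 2      # one lattice step off
    u <- competitionUnits(targetPoints(pairs)[2, ], 5, 2,
                          sc@width, sc@height)
    win <- findWinner(pairs, 2, u, pr$source, pr$target, miTol = 0,
                      miStride = 2L)
    if (sqrt(sum((win$point - truth)^2)) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("refinement recovers a 4-px control-point perturbation", {
  hits <- 0
  for (s in 0:9) {
    sc <- generateScene(s)
    w0 <- randomSmoothWarp(100 + s, maxDisplacement = 10)
    pr <- renderPair(sc, w0)
    pairs <- truth_pairs(pr)
    truth <- targetPoints(pairs)[2, ]
    pairs@xt[2] <- pairs@xt[2] + 4
    st <- somRefine(pairs, pr$source, pr$target, somParams())
    got <- targetPoints(st@bestPairs)[2, ]
    if (sqrt(sum((got - truth)^2)) <= 2) hits <- hits + 1
    # committed MI trace is non-decreasing on every seed
    expect_true(all(diff(st@miTrace) >= -1e-9))
  }
  expect_gte(hits, 8)
})

test_that("refinement is a no-op when every winner starts at its center", {
  sc <- generateScene(12, noiseSigma = 0, intensityOffset = 0)
  pr <- renderPair(sc, identityWarp(), noiseSeeds = c(1L, 1L))
  pairs <- truth_pairs(pr)
  st <- somRefine(pairs, pr$source, pr$target, somParams())
  expect_true(st@converged)
  expect_identical(st@iter, 3L)         # the stability window alone
  expect_equal(targetPoints(st@bestPairs), targetPoints(pairs))
})

test_that("the learning schedule vanishes at the iteration horizon", {
  p <- somParams(iMax = 10L)
  # EtaN(i) = eta0 (1 - i/iMax): zero displacement as i -> iMax
  eta <- p@eta0 * (1 - (p@iMax - 1) / p@iMax)
  expect_lt(eta, p@eta0 / 5)
  expect_gt(eta, 0)
})

test_that("somStep commits only non-decreasing global MI", {
  pr <- test_pair(13, maxDisplacement = 10)
  pairs <- truth_pairs(pr)
  pairs@xt[2] <- pairs@xt[2] + 4
  state <- thermoreg:::.som_init(pairs, pr$source, pr$target, somParams())
  for (k in 1:4) {
    if (state@converged) break
    state <- somStep(state, somParams(), pr$source, pr$target)
  }
  expect_true(all(diff(state@miTrace) >= -1e-9))
  expect_gte(state@bestMI, state@miTrace[1])
})

test_that("refinement never noticeably degrades an end-to-end result", {
  worsened <- 0
  for (s in 0:9) {
    sc <- generateScene(s)
    w0 <- randomSmoothWarp(100 + s, maxDisplacement = 15)
    pr <- renderPair(sc, w0)
    r0 <- runRegistration(pr$source, pr$target, refine = FALSE)
    r1 <- runRegistration(pr$source, pr$target)
    e0 <- markerError(tpsApply(forwardModel(r0), pr$landmarks$source),
                      pr$landmarks$target)$mean
    e1 <- markerError(tpsApply(forwardModel(r1), pr$landmarks$source),
                      pr$landmarks$target)$mean
    if (e1 - e0 > 0.5) worsened <- worsened + 1
  }
  expect_identical(worsened, 0)
})
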