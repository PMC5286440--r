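test_that("gradient descriptors capture direction and rotation", {
  ramp <- matrix(rep(seq(0, 1, length.out = 41), each = 41), 41, 41)
  d <- gradientDescriptor(ramp, c(20, 20), W = 9)
  expect_true(all(d@valid))
  expect_true(all(abs(d@angles) < 1e-9))   # gradient along +x

  # rotating the image 90 deg shifts angles by pi/2 (mod 2 pi)
  rot <- t(ramp)[, 41:1]                   # counter-clockwise rotation
  dr <- gradientDescriptor(rot, c(20, 20), W = 9)
  diff <- (dr@angles - d@angles) %% (2 * pi)
  expect_true(all(abs(diff - pi / 2) < 1e-9))

  # constant image: everything flagged zero-magnitude
  dc <- gradientDescriptor(matrix(0.4, 41, 41), c(20, 20), W = 9)
  expect_false(any(dc@valid))

  # border violation: descriptor unavailable
  expect_null(gradientDescriptor(ramp, c(2, 20), W = 9))
})

test_that("SAD scoring is circular, skips invalid pixels, matches oracle", {
  ramp <- matrix(rep(seq(0, 1, length.out = 41), each = 41), 41, 41)
  d <- gradientDescriptor(ramp, c(20, 20), W = 3)
  expect_identical(sadScore(d, d), 0)

  # angles 0 vs pi everywhere on a 3x3 window: maximal distance 9 * pi
  d0 <- d; d0@angles[] <- 0; d0@valid[] <- TRUE
  dpi <- d; dpi@angles[] <- pi; dpi@valid[] <- TRUE
  expect_equal(sadScore(d0, dpi), 9 * pi)

  dc <- gradientDescriptor(matrix(0.4, 41, 41), c(20, 20), W = 3)
  expect_identical(sadScore(dc, dc), Inf)

  set.seed(5)
  for (rep in 1:20) {
    a1 <- matrix(runif(25, 0, 2 * pi), 5, 5)
    a2 <- matrix(runif(25, 0, 2 * pi), 5, 5)
    v1 <- matrix(runif(25) > 0.2, 5, 5)
    v2 <- matrix(runif(25) > 0.2, 5, 5)
    g1 <- new("GradientDescriptor", angles = a1, valid = v1,
              center = c(10, 10), W = 5L)
    g2 <- new("GradientDescriptor", angles = a2, valid = v2,
              center = c(10, 10), W = 5L)
    expect_equal(sadScore(g1, g2), sad_oracle(a1, v1, a2, v2))
  }
})

test_that("relaxation matching recovers identity and pure translations", {
  sc <- generateScene(5)
  img <- renderScene(sc, noiseSeed = 3)
  det <- detectFeatures(img)
  ms <- relaxationMatch(det$points, img, img, W = 21, searchRadius = 8)
  expect_gt(length(ms), 0)
  expect_true(all(matchCosts(ms) == 0))
  expect_equal(sourcePoints(ms), targetPoints(ms))

  # translated target: every surviving match displaced by (5, 0)
  m <- pixels(img)
  shifted <- cbind(m[, 1:5] * 0, m[, 1:(ncol(m) - 5)])
  tr <- relaxationMatch(det$points, img, ThermalImage(shifted),
                        W = 21, searchRadius = 10)
  disp <- targetPoints(tr) - sourcePoints(tr)
  interior <- sourcePoints(tr)[, 1] < ncol(m) - 25
  expect_gt(mean(disp[interior, 1] == 5), 0.9)
  expect_gt(mean(disp[interior, 2] == 0), 0.9)
})

test_that("shape-context bins are exact for a single pixel and translate", {
  H <- 201; W <- 201
  skel <- matrix(FALSE, H, W)
  heat <- matrix(FALSE, H, W)
  R <- 100
  # single skeleton pixel at distance R/2, angle 45 deg from the center
  cx <- 100; cy <- 100
  off <- round(R / 2 / sqrt(2))
  skel[cy + off + 1, cx + off + 1] <- TRUE
  d <- shapeContext(c(cx, cy), skel, heat, R = R)
  r <- sqrt(2) * off
  ai <- floor((atan2(off, off) %% (2 * pi)) / (2 * pi / 12))
  ri <- floor(5 * log(r / (R / 16)) / log(16))
  expect_equal(sum(d@bins > 0), 1)
  expect_equal(d@bins[ai * 5 + ri + 1], 1)
  expect_true(all(d@bins[61:120] == 0))    # heat half empty stays zero

  # joint translation leaves the histogram unchanged
  skel2 <- matrix(FALSE, H, W)
  skel2[cy + off + 1 - 30, cx + off + 1 + 20] <- TRUE
  d2 <- shapeContext(c(cx + 20, cy - 30), skel2, heat, R = R)
  expect_identical(d2@bins, d@bins)

  # empty maps give the all-zero descriptor
  d0 <- shapeContext(c(cx, cy), heat, heat, R = R)
  expect_true(all(d0@bins == 0))
})

test_that("shape-context histograms rotate with joint 90-degree rotation", {
  set.seed(9)
  H <- 151; W <- 151
  skel <- matrix(FALSE, H, W)
  pts <- cbind(sample(30:120, 40), sample(30:120, 40))
  skel[pts] <- TRUE
  ctr <- c(75, 75)
  d <- shapeContext(ctr, skel, skel & FALSE, R = 60)
  # rotate the map by 90 deg about the center: (x, y) -> (y, -x)
  rot <- matrix(FALSE, H, W)
  idx <- which(skel, arr.ind = TRUE)
  x <- idx[, 2] - 1 - ctr[1]; y <- idx[, 1] - 1 - ctr[2]
  rot[cbind(-x + ctr[2] + 1, y + ctr[1] + 1)] <- TRUE
  dr <- shapeContext(ctr, rot, rot & FALSE, R = 60)
  # the rotation maps angle a to a - 90 deg, shifting angular bins by 3
  g <- matrix(d@bins[1:60], nrow = 5)      # [radial, angular]
  h <- matrix(dr@bins[1:60], nrow = 5)
  expect_equal(h, g[, c(4:12, 1:3)], tolerance = 1e-12)
})

test_that("chi-squared cost matches the oracle and its bounds", {
  expect_identical(scCost(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_identical(scCost(c(1, 0, 0), c(0, 1, 0)), 1)
  set.seed(13)
  for (rep in 1:20) {
    g <- runif(120); g[sample(120, 40)] <- 0
    h <- runif(120); h[sample(120, 40)] <- 0
    g[1:60] <- g[1:60] / sum(g[1:60]); g[61:120] <- g[61:120] / sum(g[61:120])
    h[1:60] <- h[1:60] / sum(h[1:60]); h[61:120] <- h[61:120] / sum(h[61:120])
    expect_equal(scCost(g, h), chi2_oracle(g, h), tolerance = 1e-12)
    expect_equal(scCost(g, h), scCost(h, g))
    expect_lte(scCost(g, h), 2 + 1e-12)
  }
  expect_error(scCost(runif(10), runif(12)), "bin counts differ")
})

test_that("assignment equals the exhaustive permutation minimum", {
  set.seed(31)
  for (n in 2:7) {
    for (rep in 1:20) {
      cost <- matrix(runif(n * n), n, n)
      sol <- solveAssignment(cost)
      expect_equal(sol$cost, brute_assignment(cost), tolerance = 1e-12)
      expect_false(any(duplicated(sol$assignment)))
    }
  }
  # rectangular: all rows assigned when rows < cols, and vice versa
  cost <- matrix(runif(12), 3, 4)
  sol <- solveAssignment(cost)
  expect_false(anyNA(sol$assignment))
  expect_equal(sol$cost, brute_assignment(cost), tolerance = 1e-12)
  solT <- solveAssignment(t(cost))
  expect_identical(sum(is.na(solT$assignment)), 1L)
})

test_that("strict matching keeps mutual best pairs passing ratio tests", {
  res <- strictMatchCosts(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE), 0.5)
  expect_equal(res$pairs, rbind(c(1, 1), c(2, 2)))

  # both assigned pairs rejected: ratio 0.9 / 1.0 > 0.5
  res2 <- strictMatchCosts(matrix(c(0.9, 1, 1, 0.9), 2, 2, byrow = TRUE),
                           0.5)
  expect_identical(nrow(res2$pairs), 0L)
})

test_that("matching vectors take per-side medians and handle absence", {
  ms <- MatchSet(xs = c(10, 20, 30, 60, 70), ys = rep(10, 5),
                 xt = c(13, 23, 33, 63, 73), yt = rep(8, 5),
                 cost = rep(0, 5), provenance = "strict")
  v <- trainMatchingVectors(ms, midlineX = 50)
  expect_equal(v$left$displacement, c(3, -2))
  expect_equal(v$right$displacement, c(3, -2))
  expect_identical(v$left$support, 3L)

  # median is robust to one outlier
  msl <- MatchSet(xs = c(1, 2, 3), ys = c(1, 2, 3),
                  xt = c(1, 2, 13), yt = c(1, 2, 13),
                  cost = rep(0, 3), provenance = "strict")
  vl <- trainMatchingVectors(msl, midlineX = 50)
  expect_equal(vl$left$displacement, c(0, 0))
  expect_null(vl$right)
})

test_that("matching-vector revision removes injected outliers", {
  set.seed(17)
  survived_true <- numeric(); removed_bad <- numeric()
  for (s in 1:10) {
    n_true <- 40; n_bad <- 20
    xs <- runif(n_true + n_bad, 30, 120)
    ys <- runif(n_true + n_bad, 30, 90)
    true_disp <- c(6, -3)
    dx <- c(rep(true_disp[1], n_true) + rnorm(n_true, 0, 1),
            runif(n_bad, -60, 60))
    dy <- c(rep(true_disp[2], n_true) + rnorm(n_true, 0, 1),
            runif(n_bad, -60, 60))
    rel <- MatchSet(xs, ys, xs + dx, ys + dy, cost = runif(n_true + n_bad),
                    provenance = "relaxed")
    vecs <- list(left = list(displacement = true_disp, support = 5L),
                 right = list(displacement = true_disp, support = 5L),
                 midlineX = 75)
    out <- reviseRelaxed(rel, vecs, tolPx = 10)
    kept <- paste(out@xs, out@ys)
    all_keys <- paste(xs, ys)
    survived_true <- c(survived_true,
                       mean(all_keys[1:n_true] %in% kept))
    bad_disp_far <- sqrt((dx - true_disp[1])^2 +
                           (dy - true_disp[2])^2)[-(1:n_true)] > 10
    removed_bad <- c(removed_bad,
                     mean(!(all_keys[-(1:n_true)][bad_disp_far] %in% kept)))
    expect_true(all(provenance(out) == "relaxed_revised"))
  }
  expect_gte(mean(survived_true), 0.95)
  expect_gte(mean(removed_bad), 0.95)
})

test_that("merging prefers strict pairs and enforces the TPS floor", {
  strict <- MatchSet(xs = c(10, 40), ys = c(10, 40), xt = c(11, 41),
                     yt = c(11, 41), cost = c(0.1, 0.1),
                     provenance = "strict")
  rel <- MatchSet(xs = c(10, 70, 90), ys = c(10, 70, 90),
                  xt = c(30, 71, 91), yt = c(30, 71, 91),
                  cost = c(5, 5, 5), provenance = "relaxed_revised")
  merged <- mergeControlPairs(strict, rel, 10)
  # duplicate source (10, 10): the strict pair's target wins
  i <- which(merged@xs == 10)
  expect_equal(merged@xt[i], 11)
  expect_length(merged, 4)

  expect_error(mergeControlPairs(strict, rel[1], 10),
               class = "thermoregUnderdetermined")
})

test_that("merged pairs are spatially spread by ANMS", {
  set.seed(23)
  n <- 100
  xs <- c(runif(n / 2, 40, 60), runif(n / 2, 0, 150))
  ys <- c(runif(n / 2, 40, 60), runif(n / 2, 0, 150))
  rel <- MatchSet(xs, ys, xs + 1, ys + 1, cost = runif(n),
                  provenance = "relaxed_revised")
  empty <- MatchSet(provenance = character())
  merged <- mergeControlPairs(empty, rel, 20, cRobust = 1)
  expect_lte(length(merged), 20)
  # min pairwise source distance >= ANMS radius of the weakest survivor
  r <- thermoreg:::.anms_radii(merged@xs, merged@ys, -merged@cost, 1)
  expect_gte(min(dist(sourcePoints(merged))) + 1e-9, min(r))
})

test_that("full matcher pins most control pairs near ground truth", {
  good <- 0; total <- 0
  for (s in 0:9) {
    pr <- test_pair(s)
    cfg <- pipelineConfig()
    detS <- detectFeatures(pr$source, cfg)
    detT <- detectFeatures(pr$target, cfg)
    rel <- relaxationMatch(detS$points, pr$source, pr$target)
    st <- strictMatch(detS$points, detT$points, detS, detT)
    if (length(st) == 0) next
    vec <- trainMatchingVectors(st, ncol(pixels(pr$source)) / 2)
    pairs <- tryCatch(
      mergeControlPairs(st, reviseRelaxed(rel, vec, 10), 40),
      thermoregUnderdetermined = function(e) NULL)
    if (is.null(pairs)) next
    truth <- applyWarp(pr$warp, sourcePoints(pairs))
    d <- sqrt(rowSums((truth - targetPoints(pairs))^2))
    good <- good + sum(d <= 3)
    total <- total + length(d)
  }
  expect_gt(total, 0)
  expect_gte(good / total, 0.9)
})
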