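test_that("constant images yield no corners", {
  expect_length(harrisCorners(ThermalImage(matrix(0.5, 48, 48))), 0)
})

test_that("bright square corners are localized within 2 px", {
  m <- matrix(0, 64, 64)
  m[21:45, 21:45] <- 1                      # vertices at (20, 20)..(44, 44)
  pts <- harrisCorners(ThermalImage(m))
  expect_gte(length(pts), 4)
  truth <- rbind(c(20, 20), c(44, 20), c(20, 44), c(44, 44))
  top4 <- coords(pts)[order(-responses(pts))[1:4], , drop = FALSE]
  for (i in 1:4) {
    d <- sqrt((top4[, 1] - truth[i, 1])^2 + (top4[, 2] - truth[i, 2])^2)
    expect_lte(min(d), 2)
  }
})

test_that("checkerboard interior vertices are detected within 2 px", {
  cell <- 16
  m <- outer(0:(4 * cell - 1), 0:(4 * cell - 1), function(r, c)
    (floor(r / cell) + floor(c / cell)) %% 2)
  pts <- harrisCorners(ThermalImage(m))
  vert <- expand.grid(x = cell * (1:3) - 0.5, y = cell * (1:3) - 0.5)
  for (i in seq_len(nrow(vert))) {
    d <- sqrt((coords(pts)[, 1] - vert$x[i])^2 +
                (coords(pts)[, 2] - vert$y[i])^2)
    expect_lte(min(d), 2)
  }
})

test_that("ANMS matches the brute-force oracle on random point sets", {
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(20:200, 1)
    x <- runif(n, 0, 300); y <- runif(n, 0, 200)
    resp <- runif(n, 0, 10)
    cr <- sample(c(0.7, 0.9, 1), 1)
    nt <- sample(5:50, 1)
    pts <- FeaturePointSet(x, y, resp)
    got <- anms(pts, nt, cr)
    oracle <- anms_oracle(x, y, resp, nt, cr)
    expect_equal(coords(got)[, 1], x[oracle$keep])
    expect_equal(coords(got)[, 2], y[oracle$keep])
    expect_equal(suppressionRadius(got), oracle$radius[oracle$keep])
  }
})

test_that("ANMS definitional cases hold", {
  one <- anms(FeaturePointSet(5, 5, 1), 1)
  expect_identical(suppressionRadius(one), Inf)

  two <- anms(FeaturePointSet(c(0, 7), c(0, 0), c(10, 1)), 2, cRobust = 1)
  expect_equal(suppressionRadius(two), c(Inf, 7))

  # nTarget beyond the set size returns everything with radii set
  all3 <- anms(FeaturePointSet(c(0, 5, 9), c(0, 0, 0), c(3, 2, 1)), 10)
  expect_length(all3, 3)
  expect_true(all(is.finite(suppressionRadius(all3)[-1])))

  # pairwise distances of survivors at c = 1 respect the smallest radius
  set.seed(4)
  pts <- FeaturePointSet(runif(80, 0, 100), runif(80, 0, 100),
                         runif(80, 1, 2))
  kept <- anms(pts, 15, cRobust = 1)
  dmin <- min(dist(coords(kept)))
  expect_gte(dmin + 1e-9, min(suppressionRadius(kept)))
})

test_that("vesselness prefers ridges over blobs and masks centerlines", {
  expect_true(all(vesselMap(matrix(0.3, 48, 48))$likelihood == 0))
  expect_false(any(vesselMap(matrix(0.3, 48, 48))$mask))

  r <- ridge_image()
  vm <- vesselMap(r, sigmaV = 2)
  # mask must cover the true centerline (dilated by the ridge width)
  center <- vm$mask[30:34, 11:86]
  expect_gte(mean(apply(center, 2, any)), 0.9)

  # equally bright ridge and isotropic blob in one frame: the ridge
  # must dominate the (jointly normalized) likelihood
  both <- ridge_image(H = 64, W = 96, y0 = 15) +
    0.8 * exp(-(outer((0:63 - 47)^2, (0:95 - 47)^2, "+")) / (2 * 1.5^2))
  lik <- vesselMap(pmin(both, 1), 2)$likelihood
  expect_gt(lik[16, 48], lik[48, 48])
})

test_that("thinning produces 1-px skeletons preserving shape", {
  bar <- matrix(FALSE, 40, 60)
  bar[18:22, 6:55] <- TRUE
  sk <- skeletonize(bar)
  # single 1-px line along the bar axis (end effects allowed)
  cols <- 9:52
  expect_true(all(colSums(sk[, cols]) == 1))
  expect_true(all(which(sk[, 30]) %in% 18:22))
  # no fully-set 2x2 block anywhere
  blocks <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -ncol(sk)]
  expect_false(any(blocks))

  expect_false(any(skeletonize(matrix(FALSE, 20, 20))))
})

test_that("junction pixels are found where branches meet", {
  # straight line: no junctions
  line <- matrix(FALSE, 21, 21); line[11, 3:19] <- TRUE
  expect_identical(nrow(skeletonIntersections(line)), 0L)

  # perfect plus: the center pixel is a junction
  pl <- matrix(FALSE, 21, 21)
  pl[11, 3:19] <- TRUE; pl[3:19, 11] <- TRUE
  raw <- skeletonIntersections(pl)
  expect_true(any(raw$x == 10 & raw$y == 10))

  # thick plus-sign -> thinned skeleton has exactly one junction cluster
  sk <- skeletonize(plus_mask())
  raw2 <- skeletonIntersections(sk)
  expect_gte(nrow(raw2), 1)
  bc <- junctionBarycenters(raw2, 8)
  expect_length(bc, 1)
  expect_lt(sqrt((coords(bc)[1] - 20)^2 + (coords(bc)[2] - 20)^2), 3)
})

test_that("junction barycenters follow the centroid and merge rules", {
  raw <- data.frame(x = c(10, 10, 11), y = c(10, 11, 10), label = 1L)
  bc <- junctionBarycenters(raw, 5)
  expect_equal(unname(coords(bc)[1, ]), c(31 / 3, 31 / 3), tolerance = 1e-9)
  expect_equal(responses(bc), 3)

  two_near <- data.frame(x = c(10, 12), y = c(10, 10), label = c(1L, 2L))
  expect_length(junctionBarycenters(two_near, 5), 1)
  two_far <- data.frame(x = c(10, 60), y = c(10, 10), label = c(1L, 2L))
  expect_length(junctionBarycenters(two_far, 5), 2)
})

test_that("generated junctions are recovered by the detector chain", {
  ok <- 0
  for (s in 0:9) {
    sc <- generateScene(s)
    img <- renderScene(sc, noiseSeed = s + 11)
    sk <- skeletonize(vesselMap(img)$mask)
    bc <- junctionBarycenters(skeletonIntersections(sk), 8)
    tj <- junctions(sc)
    if (length(bc) == 0) next
    d <- vapply(seq_len(nrow(tj)), function(i)
      min(sqrt((coords(bc)[, 1] - tj[i, 1])^2 +
                 (coords(bc)[, 2] - tj[i, 2])^2)), 0)
    if (max(d) <= 5) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("detected features stay inside image bounds and reach the floor", {
  sc <- generateScene(1)
  img <- renderScene(sc, noiseSeed = 2)
  det <- detectFeatures(img)
  xy <- coords(det$points)
  expect_true(all(xy[, 1] >= 0 & xy[, 1] <= ncol(pixels(img)) - 1))
  expect_true(all(xy[, 2] >= 0 & xy[, 2] <= nrow(pixels(img)) - 1))
  expect_gte(length(det$points), 10)
})
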