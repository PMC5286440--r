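test_that("SSIM is 1 on identity, symmetric, low on inverted masks", {
  img <- pixels(renderScene(generateScene(6), noiseSeed = 1))
  expect_equal(ssimIndex(img, img), 1, tolerance = 1e-9)

  set.seed(2)
  b <- matrix(runif(length(img)), nrow(img), ncol(img))
  expect_equal(ssimIndex(img, b), ssimIndex(b, img), tolerance = 1e-12)

  bin <- (matrix(runif(64 * 64), 64, 64) > 0.5) * 1
  expect_lt(ssimIndex(bin, 1 - bin), 0.2)
})

test_that("coincidence rate follows tolerant Jaccard and its properties", {
  m <- matrix(FALSE, 40, 40)
  m[20, 5:35] <- TRUE
  expect_equal(coincidenceRate(m, m, 0), 100)

  far <- matrix(FALSE, 40, 40); far[5, 5:35] <- TRUE
  expect_equal(coincidenceRate(m, far, 0), 0)

  # parallel 1-px lines 1 px apart coincide fully at tol 1
  shift <- matrix(FALSE, 40, 40); shift[21, 5:35] <- TRUE
  expect_equal(coincidenceRate(m, shift, 1), 100)
  expect_equal(coincidenceRate(m, shift, 0), 0)

  # symmetry and monotonicity in the tolerance
  set.seed(8)
  a <- matrix(runif(1600) > 0.95, 40, 40)
  b <- matrix(runif(1600) > 0.95, 40, 40)
  expect_equal(coincidenceRate(a, b, 2), coincidenceRate(b, a, 2))
  rates <- vapply(0:3, function(t) coincidenceRate(a, b, t), 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("canny overlay colors agreement green and disagreement by side", {
  img <- pixels(renderScene(generateScene(7), noiseSeed = 4))
  ov <- cannyOverlay(img, img)
  # identical inputs: every edge pixel is green (0, 1, 0)
  edges <- ov[, , 2] > 0
  expect_gt(sum(edges), 0)
  expect_true(all(ov[, , 1][edges] == 0))
  expect_true(all(ov[, , 3][edges] == 0))

  blank <- matrix(0, nrow(img), ncol(img))
  ov2 <- cannyOverlay(img, blank)
  lit <- ov2[, , 1] > 0 | ov2[, , 2] > 0 | ov2[, , 3] > 0
  expect_gt(sum(lit), 0)
  # only white pixels: all three channels set wherever anything is lit
  expect_true(all(ov2[, , 2][lit] == 1 & ov2[, , 3][lit] == 1))
})

test_that("marker error reports min/mean/max of Euclidean distances", {
  p <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(markerError(p, p), list(min = 0, mean = 0, max = 0, n = 3))

  e <- markerError(rbind(c(0, 0)), rbind(c(3, 4)))
  expect_equal(e$min, 5); expect_equal(e$mean, 5); expect_equal(e$max, 5)

  set.seed(14)
  pred <- matrix(runif(40, 0, 100), ncol = 2)
  truth <- matrix(runif(40, 0, 100), ncol = 2)
  d <- numeric(20)
  for (i in 1:20)
    d[i] <- sqrt(sum((pred[i, ] - truth[i, ])^2))
  got <- markerError(pred, truth)
  expect_equal(got$min, min(d)); expect_equal(got$mean, mean(d))
  expect_equal(got$max, max(d))

  # invariant under a joint rigid motion of both point sets
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  got2 <- markerError(pred %*% Rm + 5, truth %*% Rm + 5)
  expect_equal(got2$mean, got$mean, tolerance = 1e-12)
})

test_that("mutual information matches the R oracle and its bounds", {
  set.seed(21)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- matrix(runif(32 * 32), 32, 32)
  expect_equal(mutualInformation(a, b, 16), mi_oracle(a, b, 16),
               tolerance = 1e-10)
  # MI(a, a) equals the histogram entropy of a
  expect_equal(mutualInformation(a, a, 16), mi_oracle(a, a, 16),
               tolerance = 1e-10)
  expect_gte(mutualInformation(a, b, 16), 0)

  # independent noise at 32 bins on a 256 x 256 grid: MI near zero
  a2 <- matrix(runif(256 * 256), 256, 256)
  b2 <- matrix(runif(256 * 256), 256, 256)
  expect_lt(mutualInformation(a2, b2, 32), 0.05)

  # shuffling one argument cannot raise MI above self-information
  shuf <- matrix(sample(a), nrow(a), ncol(a))
  expect_lte(mutualInformation(a, shuf, 16),
             mutualInformation(a, a, 16))
})
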