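square_anchors <- cbind(c(0, 30, 0, 30, 15), c(0, 0, 30, 30, 12))

test_that("identity and affine target sets give zero bending energy", {
  m <- fitTPS(square_anchors, square_anchors, 0)
  n <- nrow(square_anchors)
  expect_lt(max(abs(m@coefX[seq_len(n)])), 1e-8)
  expect_lt(max(abs(m@coefY[seq_len(n)])), 1e-8)
  expect_equal(m@coefX[n + 1:3], c(0, 1, 0), tolerance = 1e-8)
  expect_equal(m@coefY[n + 1:3], c(0, 0, 1), tolerance = 1e-8)
  expect_equal(tpsApply(m, c(7, 9)), c(7, 9), tolerance = 1e-8)

  tr <- fitTPS(square_anchors, square_anchors +
                 matrix(c(5, -3), nrow(square_anchors), 2, byrow = TRUE), 0)
  expect_lt(max(abs(tr@coefX[seq_len(n)])), 1e-8)
  expect_equal(tpsApply(tr, c(10, 10)), c(15, 7), tolerance = 1e-8)
  expect_lt(tpsBendingEnergy(tr), 1e-12)
})

test_that("lambda = 0 interpolates random anchors to 1e-6 px", {
  set.seed(42)
  for (rep in 1:5) {
    a <- cbind(runif(10, 0, 100), runif(10, 0, 80))
    b <- a + cbind(rnorm(10, 0, 5), rnorm(10, 0, 5))
    m <- fitTPS(a, b, 0)
    got <- tpsApply(m, a)
    expect_lt(max(abs(got - b)), 1e-6)
    # orthogonality side conditions
    w <- m@coefX[1:10]
    expect_lt(max(abs(c(sum(w), sum(w * a[, 1]), sum(w * a[, 2])))), 1e-8)
    expect_gte(tpsBendingEnergy(m), 0)
  }
})

test_that("degenerate anchor sets are rejected with named errors", {
  coll <- cbind(1:6, 2 * (1:6) + 1)          # collinear
  expect_error(fitTPS(coll, coll + 1, 0), "singular|collinear")
  dup <- rbind(square_anchors, square_anchors[1, ])
  tgt <- rbind(square_anchors, square_anchors[1, ] + 5)
  expect_error(fitTPS(dup, tgt, 0), "conflicting targets")
  expect_error(fitTPS(square_anchors[1:3, ], square_anchors[1:3, ], 0),
               "at least 4")
  # exact duplicates with agreeing targets collapse and fit fine
  dup2 <- rbind(square_anchors, square_anchors[1, ])
  tgt2 <- rbind(square_anchors + 2, square_anchors[1, ] + 2)
  expect_equal(tpsApply(fitTPS(dup2, tgt2, 0), c(4, 4)), c(6, 6),
               tolerance = 1e-8)
})

test_that("backward warping shifts images by the expected translation", {
  set.seed(7)
  img <- ThermalImage(pixels(renderScene(generateScene(2), noiseSeed = 5)))
  m <- pixels(img)
  # backward model for a (5, 0) forward shift maps output to output - 5
  back <- fitTPS(square_anchors + matrix(c(5, 0), 5, 2, byrow = TRUE),
                 square_anchors, 0)
  warped <- pixels(warpImage(back, img))
  H <- nrow(m); W <- ncol(m)
  inner_r <- 11:(H - 10)
  inner_c <- 11:(W - 10)
  truth <- m[inner_r, inner_c - 5]
  got <- warped[inner_r, inner_c]
  expect_gt(stats::cor(c(truth), c(got)), 0.999)

  ident <- fitTPS(square_anchors, square_anchors, 0)
  expect_equal(pixels(warpImage(ident, img)), m, tolerance = 1e-6)
})

test_that("warp round trip through the refit inverse is close", {
  set.seed(11)
  img <- renderScene(generateScene(4), noiseSeed = 9)
  H <- nrow(pixels(img)); W <- ncol(pixels(img))
  g <- as.matrix(expand.grid(x = seq(10, W - 11, length.out = 4),
                             y = seq(10, H - 11, length.out = 4)))
  disp <- matrix(rnorm(nrow(g) * 2, 0, 3), ncol = 2)
  fwd <- fitTPS(g, g + disp, 0)
  bwd <- fitTPS(g + disp, g, 0)
  once <- warpImage(bwd, img)         # apply forward warp to the image
  back <- warpImage(fwd, once)        # and undo it
  inner <- pixels(back)[16:(H - 15), 16:(W - 15)] -
    pixels(img)[16:(H - 15), 16:(W - 15)]
  expect_lt(mean(abs(inner)), 0.02)
})

test_that("TPS models serialize to JSON and back", {
  set.seed(3)
  a <- cbind(runif(6, 0, 50), runif(6, 0, 50))
  m <- fitTPS(a, a + rnorm(12), 0)
  f <- withr::local_tempfile(fileext = ".json")
  tpsToJson(m, f)
  back <- tpsFromJson(f)
  p <- cbind(runif(5, 0, 50), runif(5, 0, 50))
  expect_equal(tpsApply(back, p), tpsApply(m, p), tolerance = 1e-12)
})
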