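cfg <- lossConfig()

test_that("local SSIM map matches the direct per-patch formula", {
  set.seed(11)
  x <- matrix(rnorm(16 * 16, sd = 0.3), 16)
  y <- x + matrix(rnorm(16 * 16, sd = 0.1), 16)
  s <- localSSIMMap(x, y, cfg)
  # interior pixel against a hand-extracted 7x7 patch pair
  px <- x[5:11, 5:11]; py <- y[5:11, 5:11]
  expect_equal(s[8, 8], ssimOfPatches(px, py, cfg@c1, cfg@c2), tolerance = 1e-9)
  # whole map (including mirror-padded boundary) against the loop oracle
  expect_equal(s, ssimMapOracle(x, y, cfg), tolerance = 1e-9)
})

test_that("SSIM of identical slices is one and range stays within [-1, 1]", {
  set.seed(12)
  for (rep in 1:5) {
    x <- matrix(rnorm(144, sd = runif(1, 0.05, 0.6)), 12)
    expect_equal(max(abs(localSSIMMap(x, x, cfg) - 1)), 0, tolerance = 1e-9)
    y <- matrix(rnorm(144, sd = runif(1, 0.05, 0.6)), 12)
    s <- localSSIMMap(x, y, cfg)
    expect_true(all(s >= -1 - 1e-9 & s <= 1 + 1e-9))
  }
})

test_that("constant slices reduce to the closed-form luminance term", {
  a <- -0.87; b <- -0.31
  s <- localSSIMMap(matrix(a, 10, 10), matrix(b, 10, 10), cfg)
  expect_equal(as.numeric(s), rep((2 * a * b + cfg@c1) / (a^2 + b^2 + cfg@c1), 100),
               tolerance = 1e-12)
})

test_that("shape mismatch raises an error", {
  expect_error(localSSIMMap(matrix(0, 8, 8), matrix(0, 8, 9)), "shape")
  expect_error(ssimWeightedL1(matrix(0, 8, 8), matrix(0, 8, 8),
                              matrix(0, 9, 8)), "shape")
})

test_that("thresholding zeroes exactly the sub-threshold values", {
  s <- matrix(c(0.4, 0.5, 0.49999, 1, -0.2, 0.7), 2, 3)
  w <- ssimWeightMap(s, 0.5)
  expect_equal(w, matrix(c(0, 0.5, 0, 1, 0, 0.7), 2, 3))
  expect_equal(ssimWeightMap(matrix(1, 4, 4), 0.5), matrix(1, 4, 4))
  sPos <- matrix(runif(16), 4)
  expect_equal(ssimWeightMap(sPos, 0), sPos)   # threshold vacuous
})

test_that("SSIM-weighted L1 equals the explicit double-loop sum", {
  set.seed(13)
  x <- matrix(rnorm(64, sd = 0.3), 8); y <- x + matrix(rnorm(64, sd = 0.2), 8)
  gx <- matrix(runif(64, -1, 1), 8)
  w <- ssimWeightMap(localSSIMMap(x, y, cfg), cfg@alpha)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + w[i, j] * abs(gx[i, j] - y[i, j])
  expect_equal(ssimWeightedL1(x, y, gx, cfg), acc / 64, tolerance = 1e-12)
  expect_equal(ssimWeightedL1(x, y, y, cfg), 0)
})

test_that("an all-zero weight map makes the loss insensitive to the output", {
  set.seed(14)
  # textured x against a flat y with a separated mean: the covariance term
  # collapses and the luminance term is negative, so SSIM < alpha everywhere
  x <- matrix(rnorm(100, mean = -0.6, sd = 0.3), 10)
  y <- matrix(0.4, 10, 10)
  w <- ssimWeightMap(localSSIMMap(x, y, cfg), cfg@alpha)
  expect_true(all(w == 0))  # fixture sanity
  g1 <- matrix(runif(100, -1, 1), 10); g2 <- matrix(runif(100, -1, 1), 10)
  expect_equal(ssimWeightedL1(x, y, g1, cfg), 0)
  expect_equal(ssimWeightedL1(x, y, g2, cfg), 0)
})

test_that("weighted L1 is monotone nonincreasing in the threshold", {
  set.seed(15)
  x <- matrix(rnorm(144, sd = 0.3), 12); y <- x + matrix(rnorm(144, sd = 0.25), 12)
  gx <- matrix(runif(144, -1, 1), 12)
  vals <- vapply(seq(0, 1, by = 0.1), function(a)
    ssimWeightedL1(x, y, gx, lossConfig(alpha = a)), 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("perturbing the output only inside a zero-weight region leaves the loss unchanged", {
  set.seed(16)
  x <- matrix(rnorm(256, sd = 0.3), 16); y <- x + matrix(rnorm(256, sd = 0.05), 16)
  # destroy agreement in a patch so its weights drop below threshold
  x[5:10, 5:10] <- x[5:10, 5:10] + 1.2
  w <- ssimWeightMap(localSSIMMap(x, y, cfg), cfg@alpha)
  zero <- which(w == 0, arr.ind = TRUE)
  expect_gt(nrow(zero), 0)  # fixture sanity: the damaged patch is sub-threshold
  gx <- matrix(runif(256, -1, 1), 16)
  gx2 <- gx
  gx2[zero] <- runif(nrow(zero), -1, 1)
  expect_identical(ssimWeightedL1(x, y, gx, cfg),
                   ssimWeightedL1(x, y, gx2, cfg))
})

test_that("cycle-consistency loss matches brute force and its special cases", {
  set.seed(17)
  x <- matrix(rnorm(36), 6); y <- matrix(rnorm(36), 6)
  expect_equal(cycleConsistencyLoss(x, y, x, y), 0)
  expect_equal(cycleConsistencyLoss(x, y, x + 0.3, y), 0.3, tolerance = 1e-12)
  fgx <- matrix(rnorm(36), 6); gfy <- matrix(rnorm(36), 6)
  expect_equal(cycleConsistencyLoss(x, y, fgx, gfy),
               sum(abs(fgx - x)) / 36 + sum(abs(gfy - y)) / 36,
               tolerance = 1e-12)
})

test_that("least-squares adversarial terms match elementwise evaluation", {
  expect_equal(adversarialLosses(matrix(0.3, 2, 2), matrix(1, 2, 2))$gen, 0)
  expect_equal(adversarialLosses(matrix(1, 2, 2), matrix(0, 2, 2))$disc, 0)
  set.seed(18)
  dr <- matrix(rnorm(25), 5); df <- matrix(rnorm(25), 5)
  a <- adversarialLosses(dr, df)
  expect_equal(a$gen, sum((df - 1)^2) / 25, tolerance = 1e-12)
  expect_equal(a$disc, sum((dr - 1)^2) / 25 + sum(df^2) / 25, tolerance = 1e-12)
})

test_that("total generator loss composes parts with the lambda weights", {
  z <- totalGeneratorLoss(list(ssimWeightedL1 = 0, cycle = 0, adversarial = 0))
  expect_equal(z$total, 0)
  only <- totalGeneratorLoss(list(ssimWeightedL1 = 0.7, cycle = 0.3,
                                  adversarial = 0.1),
                             lossConfig(lambdaSSIM = 1, lambdaCycle = 0,
                                        lambdaAdv = 0))
  expect_equal(only$total, 0.7)
  mix <- totalGeneratorLoss(list(ssimWeightedL1 = 0.2, cycle = 0.05,
                                 adversarial = 0.5),
                            lossConfig(lambdaSSIM = 1, lambdaCycle = 10,
                                       lambdaAdv = 1))
  expect_equal(mix$total, 1.2, tolerance = 1e-12)
  expect_error(totalGeneratorLoss(list(ssimWeightedL1 = NaN, cycle = 0,
                                       adversarial = 0)), "finite")
})

test_that("loss terms are equivariant under simultaneous pixel shuffles", {
  set.seed(19)
  x <- matrix(rnorm(64, sd = 0.3), 8); y <- x + matrix(rnorm(64, sd = 0.2), 8)
  gx <- matrix(runif(64, -1, 1), 8)
  p <- sample(64)
  perm <- function(m) matrix(as.numeric(m)[p], 8)
  # weighted L1 with an explicit weight map (the map itself is local, so it
  # is supplied rather than recomputed after shuffling)
  w <- ssimWeightMap(localSSIMMap(x, y, cfg), cfg@alpha)
  expect_equal(ssimWeightedL1(x, y, gx, cfg, weights = w),
               ssimWeightedL1(perm(x), perm(y), perm(gx), cfg,
                              weights = perm(w)), tolerance = 1e-12)
  expect_equal(cycleConsistencyLoss(x, y, gx, gx),
               cycleConsistencyLoss(perm(x), perm(y), perm(gx), perm(gx)),
               tolerance = 1e-12)
  a1 <- adversarialLosses(x, gx); a2 <- adversarialLosses(perm(x), perm(gx))
  expect_equal(a1$gen, a2$gen, tolerance = 1e-12)
  expect_equal(a1$disc, a2$disc, tolerance = 1e-12)
})
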