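test_that("intensity normalization maps the HU window onto [-1, 1]", {
  vox <- array(0, c(4, 4, 2))
  vox[1:5] <- c(-1000, 2000, 500, -1000, 2000)
  vol <- imageVolume(vox, c(3, 3, 3))
  pre <- preprocessVolume(vol, preprocessSpec(targetSize = 4L, targetPixelMM = 3))
  expect_equal(pre$slices[1:5], c(-1, 1, 0, -1, 1))
  # out-of-window values clip first
  vox2 <- array(3000, c(4, 4, 1))
  p2 <- preprocessVolume(imageVolume(vox2, c(3, 3, 3)),
                         preprocessSpec(targetSize = 4L, targetPixelMM = 3))
  expect_equal(unique(as.numeric(p2$slices)), 1)
})

test_that("postprocess inverts preprocess exactly on a matching grid", {
  set.seed(21)
  vox <- array(runif(8 * 8 * 3, -1024, 3071), c(8, 8, 3))
  vol <- imageVolume(vox, c(3, 3, 3), c(5, 6, 7))
  pre <- preprocessVolume(vol, preprocessSpec(targetSize = 8L, targetPixelMM = 3))
  back <- postprocessSlices(pre$slices, pre$geom)
  expect_equal(voxels(back), pmin(pmax(vox, -1000), 2000), tolerance = 1e-9)
  expect_equal(spacing(back), spacing(vol))
  expect_equal(origin(back), origin(vol))
  # all -1 slices map to all -1000 HU
  allLow <- postprocessSlices(array(-1, dim(pre$slices)), pre$geom)
  expect_equal(unique(as.numeric(voxels(allLow))), -1000)
})

test_that("resampling round trip stays within the double-resample tolerance", {
  set.seed(22)
  # smooth field: CT-like spatial correlation, so interpolation error is small
  vox <- sctgan:::.gaussSmooth3(array(runif(12 * 12 * 2, -500, 1500),
                                      c(12, 12, 2)), c(1.5, 1.5, 0))
  vol <- imageVolume(vox, c(4, 4, 4))
  spec <- preprocessSpec(targetSize = 16L, targetPixelMM = 3)
  pre <- preprocessVolume(vol, spec)
  back <- postprocessSlices(pre$slices, pre$geom)
  # oracle: two successive bilinear resamples of the clipped original,
  # written directly against the interpolation helper
  clip <- pmin(pmax(vox, -1000), 2000)
  res1 <- sctgan:::.resampleSlices(clip, c(4, 4), c(0, 0), 16L, 3, -1000)
  cx <- (12 - 1) / 2 * 4
  tOrigin <- c(cx - (16 - 1) / 2 * 3, cx - (16 - 1) / 2 * 3)
  x <- (seq_len(12) - 1) * 4
  P <- cbind(rep(x, times = 12), rep(x, each = 12), 0)
  oracle <- array(0, dim(vox))
  for (k in 1:2)
    oracle[, , k] <- sctgan:::.interp3(array(res1[, , k], c(16, 16, 1)),
                                       c(3, 3, 1), c(tOrigin, 0), P,
                                       fill = -1000)
  expect_equal(voxels(back), oracle, tolerance = 1e-9)
  # away from the FOV border (where the target grid's air fill blends in),
  # the round trip is interpolation-limited
  inner <- 2:11
  expect_lt(mean(abs(voxels(back) - clip)[inner, inner, ]), 15)
})

test_that("learning-rate schedule is flat then linear to zero", {
  cfg <- trainConfig()
  expect_equal(lrAtEpoch(10, cfg), 2e-4)
  expect_equal(lrAtEpoch(20, cfg), 2e-4)
  expect_equal(lrAtEpoch(30, cfg), 1e-4)
  expect_equal(lrAtEpoch(40, cfg), 0)
  lrs <- vapply(1:40, lrAtEpoch, 0, cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
  # the linear segment extrapolates back to the base rate at the breakpoint
  expect_equal(cfg@baseLR * (cfg@epochs - 20) / (cfg@epochs - 20), lrAtEpoch(20, cfg))
  expect_error(lrAtEpoch(0, cfg), "range")
  expect_error(lrAtEpoch(41, cfg), "range")
})

test_that("generator maps slices shape-preservingly with bounded output", {
  G <- buildGenerator(toyGeneratorSpec(), seed = 1)
  x <- matrix(rnorm(64 * 64, sd = 0.5), 64)
  y <- applyNetwork(G, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(abs(y) <= 1))
  expect_error(applyNetwork(G, matrix(0, 63, 64)), "divisible")
})

test_that("toy generator parameter count matches the closed-form tally", {
  G <- buildGenerator(toyGeneratorSpec(), seed = 0)
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  inorm <- function(ch) 2 * ch
  res <- function(ch) 2 * conv(3, ch, ch) + 2 * inorm(ch)
  expected <- conv(3, 1, 8) + inorm(8) + res(8) +       # encoder level 1
    conv(3, 8, 16) + inorm(16) + res(16) +              # encoder level 2
    conv(3, 16, 8) + inorm(8) +                         # upsample conv
    conv(3, 16, 8) + inorm(8) +                         # skip fusion
    res(8) +                                            # decoder res block
    conv(3, 8, 1)                                       # output head
  expect_equal(sum(vapply(G$params, length, 0L)), expected)
})

test_that("same-seed builds are identical; different seeds differ", {
  a <- buildGenerator(toyGeneratorSpec(), seed = 9)
  b <- buildGenerator(toyGeneratorSpec(), seed = 9)
  expect_identical(a$params, b$params)
  c <- buildGenerator(toyGeneratorSpec(), seed = 10)
  expect_false(identical(a$params, c$params))
  d1 <- buildDiscriminator(discriminatorSpec(2L, 8L), seed = 9)
  d2 <- buildDiscriminator(discriminatorSpec(2L, 8L), seed = 9)
  expect_identical(d1$params, d2$params)
})

test_that("discriminator score-map extent follows stride arithmetic", {
  # reference stack: 3 stride-2 layers + 2 stride-1 layers, all 4x4 kernels:
  # 256 -> 128 -> 64 -> 32 -> 31 -> 30
  D <- buildDiscriminator(discriminatorSpec(nStride2 = 3L, baseChannels = 4L),
                          seed = 2)
  expect_identical(dim(applyNetwork(D, matrix(0, 256, 256))), c(30L, 30L))
  D2 <- buildDiscriminator(discriminatorSpec(nStride2 = 2L, baseChannels = 8L),
                           seed = 2)
  expect_identical(dim(applyNetwork(D2, matrix(0, 64, 64))), c(14L, 14L))
  expect_error(applyNetwork(D, matrix(0, 4, 4)), "receptive field")
})

test_that("zeroed discriminator weights give a constant score map", {
  D <- buildDiscriminator(discriminatorSpec(2L, 4L), seed = 0)
  D$params <- lapply(D$params, function(p) p * 0)
  y <- applyNetwork(D, matrix(rnorm(32 * 32), 32))
  expect_equal(length(unique(as.numeric(y))), 1L)
})

test_that("a short training run is bitwise reproducible", {
  co <- makeTrainingCohort(2, seed = 3, spec = tinySpec())
  cfg <- trainConfig(epochs = 2L, constantLREpochs = 1L, batchSize = 4L,
                     seed = 11L)
  pre <- preprocessSpec(targetSize = 32L, targetPixelMM = 6)
  m1 <- trainCycleGAN(co, trainCfg = cfg, preSpec = pre)
  m2 <- trainCycleGAN(co, trainCfg = cfg, preSpec = pre)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$G$params, m2$G$params)
  expect_true(all(is.finite(as.matrix(m1$history[-1]))))
  expect_equal(nrow(m1$history), 2L)
})

test_that("ssim/adversarial weights at zero reduce to an independently coded cycle-only loop", {
  co <- makeTrainingCohort(1, seed = 5, spec = tinySpec())
  lossCfg <- lossConfig(lambdaSSIM = 0, lambdaAdv = 0, lambdaCycle = 10)
  cfg <- trainConfig(epochs = 1L, constantLREpochs = 1L, batchSize = 4L,
                     valFraction = 0, seed = 21L)
  pre <- preprocessSpec(targetSize = 32L, targetPixelMM = 6)
  m <- trainCycleGAN(co, lossCfg = lossCfg, trainCfg = cfg, preSpec = pre)

  # independent cycle-only loop: same RNG choreography, own update math
  ns <- asNamespace("sctgan")
  set.seed(21L)
  xs <- preprocessVolume(co[[1]]@cbct, pre)$slices
  ys <- preprocessVolume(co[[1]]@registeredCT, pre)$slices
  n <- dim(xs)[3]
  for (k in seq_len(n)) localSSIMMap(xs[, , k], ys[, , k], lossCfg) # RNG-free
  perm <- sample.int(n)
  trainIdx <- sort(perm)
  G <- buildGenerator(toyGeneratorSpec(), seed = 22L)
  Fb <- buildGenerator(toyGeneratorSpec(), seed = 23L)
  DY <- buildDiscriminator(discriminatorSpec(2L, 16L), seed = 24L)
  DX <- buildDiscriminator(discriminatorSpec(2L, 16L), seed = 25L)
  optG <- ns$.adamInit(G$params); optF <- ns$.adamInit(Fb$params)
  optDY <- ns$.adamInit(DY$params); optDX <- ns$.adamInit(DX$params)
  ord <- sample(trainIdx)
  cyc <- c()
  for (bi in seq_len(ceiling(length(ord) / 4))) {
    idx <- ord[((bi - 1) * 4 + 1):min(bi * 4, length(ord))]
    x <- array(xs[, , idx], c(32, 32, 1, length(idx)))
    y <- array(ys[, , idx], c(32, 32, 1, length(idx)))
    fG <- ns$.netForward(x, G$ops, G$params)
    fF <- ns$.netForward(y, Fb$ops, Fb$params)
    # discriminators still step (their losses do not touch the generators)
    for (du in list(list(p = "DY", real = y, fake = fG$y),
                    list(p = "DX", real = x, fake = fF$y))) {
      net <- get(if (du$p == "DY") "DY" else "DX")
      fr <- ns$.netForward(du$real, net$ops, net$params)
      ff <- ns$.netForward(du$fake, net$ops, net$params)
      gr <- ns$.addGrads(
        ns$.netBackward(2 * (fr$y - 1) / length(fr$y), net$ops, fr$caches,
                        net$params)$grads,
        ns$.netBackward(2 * ff$y / length(ff$y), net$ops, ff$caches,
                        net$params)$grads)
      if (du$p == "DY") {
        st <- ns$.adamStep(DY$params, gr, optDY, 2e-4)
        DY$params <- st$params; optDY <- st$state
      } else {
        st <- ns$.adamStep(DX$params, gr, optDX, 2e-4)
        DX$params <- st$params; optDX <- st$state
      }
    }
    fCyc <- ns$.netForward(fG$y, Fb$ops, Fb$params)
    gCyc <- ns$.netForward(fF$y, G$ops, G$params)
    ns$.netForward(fG$y, DY$ops, DY$params)  # mirrored forward (unused here)
    ns$.netForward(fF$y, DX$ops, DX$params)
    cyc <- c(cyc, mean(abs(fCyc$y - x)) + mean(abs(gCyc$y - y)))
    nEl <- length(x)
    bG2 <- ns$.netBackward(10 * sign(gCyc$y - y) / nEl, G$ops, gCyc$caches,
                           G$params)
    bF2 <- ns$.netBackward(10 * sign(fCyc$y - x) / nEl, Fb$ops, fCyc$caches,
                           Fb$params)
    gradsG <- ns$.addGrads(bG2$grads,
      ns$.netBackward(bF2$dx, G$ops, fG$caches, G$params)$grads)
    gradsF <- ns$.addGrads(bF2$grads,
      ns$.netBackward(bG2$dx, Fb$ops, fF$caches, Fb$params)$grads)
    st <- ns$.adamStep(G$params, gradsG, optG, 2e-4)
    G$params <- st$params; optG <- st$state
    st <- ns$.adamStep(Fb$params, gradsF, optF, 2e-4)
    Fb$params <- st$params; optF <- st$state
  }
  expect_equal(m$history$cycle[1], mean(cyc), tolerance = 1e-12)
  expect_equal(m$G$params, G$params, tolerance = 1e-12)
})

test_that("inference is deterministic, geometry-preserving and HU-bounded", {
  co <- makeTrainingCohort(1, seed = 6, spec = tinySpec())
  cfg <- trainConfig(epochs = 1L, constantLREpochs = 1L, seed = 2L)
  pre <- preprocessSpec(targetSize = 32L, targetPixelMM = 6)
  m <- trainCycleGAN(co, trainCfg = cfg, preSpec = pre)
  s1 <- inferSCT(co[[1]]@cbct, m)
  s2 <- inferSCT(co[[1]]@cbct, m)
  expect_identical(voxels(s1), voxels(s2))
  expect_identical(gridDim(s1), gridDim(co[[1]]@cbct))
  expect_equal(spacing(s1), spacing(co[[1]]@cbct))
  expect_true(all(voxels(s1) >= -1000 & voxels(s1) <= 2000))
})

test_that("inference is translation-consistent across identical slices", {
  co <- makeTrainingCohort(1, seed = 6, spec = tinySpec())
  cfg <- trainConfig(epochs = 1L, constantLREpochs = 1L, seed = 2L)
  pre <- preprocessSpec(targetSize = 32L, targetPixelMM = 6)
  m <- trainCycleGAN(co, trainCfg = cfg, preSpec = pre)
  sl <- voxels(co[[1]]@cbct)[, , 4]
  rep4 <- imageVolume(array(rep(sl, 4), c(dim(sl), 4)), spacing(co[[1]]@cbct))
  out <- voxels(inferSCT(rep4, m))
  for (k in 2:4) expect_equal(out[, , k], out[, , 1], tolerance = 1e-12)
})
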