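test_that("phantom generation is deterministic and masks are contained", {
  spec <- tinySpec()
  a <- makePhantomCT(spec, seed = 5)
  b <- makePhantomCT(spec, seed = 5)
  expect_identical(voxels(a$ct), voxels(b$ct))
  expect_identical(masks(a$structures), masks(b$structures))
  body <- a$structures[["body"]]
  for (nm in setdiff(names(masks(a$structures)), "body"))
    expect_true(all(!a$structures[[nm]] | body), info = nm)
})

test_that("zero-sigma structures paint their exact mean HU", {
  spec <- tinySpec()
  spec@structures <- lapply(spec@structures, function(s) { s$sd <- 0; s })
  ph <- makePhantomCT(spec, seed = 2)
  for (nm in c("femur_left", "bladder", "rectal_gas")) {
    vals <- voxels(ph$ct)[ph$structures[[nm]]]
    expect_equal(unique(vals), spec@structures[[nm]]$hu, info = nm)
  }
})

test_that("per-structure sample means fall within 3 sigma / sqrt(n)", {
  spec <- phantomSpec()
  ph <- makePhantomCT(spec, seed = 31)
  painted <- masks(ph$structures)
  # the body mask is the full ellipsoid by containment convention; its
  # painted region excludes the overlying organs
  organUnion <- Reduce(`|`, painted[setdiff(names(painted), "body")])
  painted$body <- painted$body & !organUnion
  for (nm in names(painted)) {
    vals <- voxels(ph$ct)[painted[[nm]]]
    s <- spec@structures[[nm]]
    expect_lt(abs(mean(vals) - s$hu),
              max(3 * s$sd / sqrt(length(vals)), 1e-9),
              label = paste(nm, "mean deviation"))
  }
})

test_that("equal-priority overlap is rejected naming the colliding pair", {
  spec <- tinySpec()
  spec@structures$bladder$center <- spec@structures$prostate$center
  spec@centerJitterMM <- 0
  expect_error(makePhantomCT(spec, seed = 1), "bladder.*prostate")
})

test_that("zero-strength degradation reproduces the CT exactly", {
  spec <- tinySpec(cuppingHU = 0, noiseSD = 0, streakCount = 0L,
                   streakIntensity = 0, huShift = 0)
  ph <- makePhantomCT(spec, seed = 3)
  cbct <- degradeToCBCT(ph$ct, spec, seed = 99)
  expect_identical(voxels(cbct), voxels(ph$ct))
})

test_that("pure cupping degradation equals the analytic bias field", {
  spec <- tinySpec(cuppingHU = 45, noiseSD = 0, streakCount = 0L,
                   streakIntensity = 0, huShift = 0)
  ph <- makePhantomCT(spec, seed = 3)
  cbct <- degradeToCBCT(ph$ct, spec, seed = 99)
  field <- cuppingField(gridDim(ph$ct), spacing(ph$ct), origin(ph$ct), 45)
  expected <- pmin(pmax(voxels(ph$ct) + field, -1024), 3071)
  expect_equal(voxels(cbct), expected, tolerance = 1e-12)
})

test_that("degradation error grows with each artifact strength", {
  base <- list(cuppingHU = 0, noiseSD = 0, streakCount = 0L,
               streakIntensity = 0, huShift = 0)
  ph <- makePhantomCT(do.call(tinySpec, base), seed = 3)
  maeOver <- function(args) {
    mean(vapply(1:5, function(s) {
      cbct <- degradeToCBCT(ph$ct, do.call(tinySpec, args), seed = s)
      mean(abs(voxels(cbct) - voxels(ph$ct)))
    }, 0))
  }
  for (knob in list(list(name = "noiseSD", vals = c(0, 20, 40)),
                    list(name = "cuppingHU", vals = c(0, 30, 60)),
                    list(name = "huShift", vals = c(0, 20, 40)),
                    list(name = "streakIntensity", vals = c(0, 30, 60)))) {
    maes <- vapply(knob$vals, function(v) {
      args <- base; args[[knob$name]] <- v
      if (knob$name == "streakIntensity") args$streakCount <- 8L
      maeOver(args)
    }, 0)
    expect_true(all(diff(maes) > 0), label = paste("MAE increasing in", knob$name))
  }
})

test_that("registered CT with zero displacement and no mismatch is the identity", {
  spec <- tinySpec(maxDisplacementMM = 0, mismatchStructure = NA_character_)
  ph <- makePhantomCT(spec, seed = 4)
  reg <- makeRegisteredCT(ph$ct, ph$structures, spec, seed = 4)
  expect_identical(voxels(reg$registeredCT), voxels(ph$ct))
  expect_false(any(reg$mismatchMask))
})

test_that("requesting a mismatch with a zero displacement bound errors", {
  spec <- tinySpec(maxDisplacementMM = 0)
  ph <- makePhantomCT(spec, seed = 4)
  expect_error(makeRegisteredCT(ph$ct, ph$structures, spec, seed = 4),
               "displacement bound")
})

test_that("the mismatch region is replaced by tissue and the field is bounded", {
  spec <- tinySpec()
  ph <- makePhantomCT(spec, seed = 6)
  reg <- makeRegisteredCT(ph$ct, ph$structures, spec, seed = 6)
  m <- reg$mismatchMask
  expect_true(any(m))
  expect_identical(m, ph$structures[["rectal_gas"]])
  inside <- mean(abs(voxels(reg$registeredCT) - voxels(ph$ct))[m])
  outside <- mean(abs(voxels(reg$registeredCT) - voxels(ph$ct))[
    ph$structures[["body"]] & !m])
  expect_gt(inside, 500)
  expect_lt(outside, 100)  # bounded by the 4 mm smooth deformation
  nrm <- sqrt(reg$displacement[, , , 1]^2 + reg$displacement[, , , 2]^2 +
              reg$displacement[, , , 3]^2)
  expect_lte(max(nrm), spec@maxDisplacementMM + 1e-12)
})

test_that("single-beam dose on a uniform water phantom follows exp(-mu z)", {
  dims <- c(24L, 24L, 4L); sp <- c(4, 4, 4)
  ct <- imageVolume(array(0, dims), sp)  # 0 HU -> rED 1
  spec <- phantomSpec(dim = dims, spacing = sp, doseStepMM = 0.5,
                      beams = list(list(angleDeg = 0, widthMM = 1e6,
                                        entranceDose = 2, mu = 0.01)))
  dose <- makeDose(ct, spec)
  # central-axis voxels: beam travels +y, entering at the voxel-centre
  # boundary y = 0 (interpolation support starts there)
  i <- 12L; k <- 2L
  for (j in c(4L, 12L, 20L)) {
    depth <- (j - 1) * sp[2]
    expect_equal(doseValues(dose)[i, j, k],
                 2 * exp(-0.01 * depth) *
                   exp(-((i - 12.5) * 4)^2 / (2 * (1e6 / 2.3548)^2)),
                 tolerance = 0.02, label = paste("depth", depth))
  }
})

test_that("zero entrance dose yields a zero grid and dose is linear in it", {
  spec <- tinySpec()
  ph <- makePhantomCT(spec, seed = 7)
  z <- spec; z@beams <- lapply(z@beams, function(b) { b$entranceDose <- 0; b })
  expect_equal(max(doseValues(makeDose(ph$ct, z))), 0)
  d1 <- makeDose(ph$ct, spec)
  k3 <- spec; k3@beams <- lapply(k3@beams, function(b) {
    b$entranceDose <- 3 * b$entranceDose; b })
  d3 <- makeDose(ph$ct, k3)
  expect_equal(doseValues(d3), 3 * doseValues(d1), tolerance = 1e-12)
})

test_that("opposed beams on a mirror-symmetric phantom give a symmetric dose", {
  dims <- c(16L, 16L, 4L); sp <- c(4, 4, 4)
  set.seed(8)
  half <- array(rnorm(8 * 16 * 4, mean = 20, sd = 100), c(16, 8, 4))
  vox <- array(0, dims)
  vox[, 1:8, ] <- half
  vox[, 16:9, ] <- half   # mirror about the y midplane
  ct <- imageVolume(pmin(pmax(vox, -1000), 2000), sp)
  spec <- phantomSpec(dim = dims, spacing = sp, doseStepMM = 1,
                      beams = list(list(angleDeg = 0, widthMM = 30,
                                        entranceDose = 1, mu = 0.005),
                                   list(angleDeg = 180, widthMM = 30,
                                        entranceDose = 1, mu = 0.005)))
  d <- doseValues(makeDose(ct, spec))
  expect_equal(d, d[, 16:1, ], tolerance = 1e-9)
})

test_that("beam isocentre outside the grid errors", {
  ct <- imageVolume(array(0, c(8, 8, 4)), c(4, 4, 4))
  spec <- phantomSpec(dim = c(8L, 8L, 4L), spacing = c(4, 4, 4),
                      beams = list(list(angleDeg = 0, widthMM = 30,
                                        entranceDose = 1, mu = 0.005,
                                        isoOffsetMM = c(500, 0, 0))))
  expect_error(makeDose(ct, spec), "outside the grid")
})

test_that("contour perturbation honours its modes and identities", {
  cube <- array(FALSE, c(20, 20, 20))
  cube[6:15, 6:15, 6:15] <- TRUE
  for (mode in c("dilate", "erode", "boundary_noise", "shift"))
    expect_identical(perturbContour(cube, mode, 0, seed = 1), cube)
  expect_error(perturbContour(cube, "twist", 1), "unknown")
  d1 <- perturbContour(cube, "dilate", 1)
  expect_equal(sum(d1), 12^3)                       # box SE: 10^3 -> 12^3
  expect_equal(dice(cube, d1), 2 * 1000 / (1000 + 1728), tolerance = 1e-12)
  e1 <- perturbContour(cube, "erode", 1)
  expect_lt(sum(e1), sum(cube))                     # strict volume decrease
  expect_equal(sum(e1), 8^3)
  set.seed(1)
  bn <- perturbContour(cube, "boundary_noise", 0.5, seed = 7)
  expect_false(identical(bn, cube))
  expect_identical(perturbContour(cube, "boundary_noise", 0.5, seed = 7), bn)
  sh <- perturbContour(cube, "shift", 6, seed = 3, spacing = c(2, 2, 2))
  expect_equal(sum(sh), sum(cube))                  # pure translation (interior)
})

test_that("cohort builder mixes matched and mismatched samples deterministically", {
  co <- makeTrainingCohort(4, seed = 1, spec = tinySpec(),
                           mismatchFraction = 0.5)
  hasMis <- vapply(co, function(s) any(s@mismatchMask), TRUE)
  expect_equal(sum(hasMis), 2)
  co2 <- makeTrainingCohort(4, seed = 1, spec = tinySpec(),
                            mismatchFraction = 0.5)
  expect_identical(vapply(co, function(s) sum(voxels(s@cbct)), 0),
                   vapply(co2, function(s) sum(voxels(s@cbct)), 0))
})
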