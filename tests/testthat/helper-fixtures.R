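# Shared fixtures, all generated in code.

# Coarse phantom (same 192 x 192 x 48 mm anatomy on a 32 x 32 x 8 grid):
# fast enough for per-test generation.
tinySpec <- function(...) {
  phantomSpec(dim = c(32L, 32L, 8L), spacing = c(6, 6, 6), doseStepMM = 3, ...)
}

# Random blob mask: union of a few random balls, possibly empty-safe.
randMask <- function(dims, seed, nBlobs = 3, rFrac = c(0.15, 0.35)) {
  set.seed(seed)
  m <- array(FALSE, dims)
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  for (b in seq_len(nBlobs)) {
    c0 <- runif(3, 0.25, 0.75) * dims
    r <- runif(1, rFrac[1], rFrac[2]) * min(dims)
    d2 <- (g$i - c0[1])^2 + (g$j - c0[2])^2 + (g$k - c0[3])^2
    m <- m | array(d2 <= r^2, dims)
  }
  if (!any(m)) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                 ceiling(dims[3] / 2)] <- TRUE
  m
}

# Smooth positive dose field with a peaked centre, scaled to a given max.
smoothDoseField <- function(dims, seed, maxGy = 2, sigmaVox = 3) {
  set.seed(seed)
  arr <- array(rnorm(prod(dims)), dims)
  arr <- sctgan:::.gaussSmooth3(arr, rep(sigmaVox, 3))
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  peak <- exp(-(((g$i - dims[1] / 2) / (dims[1] / 3))^2 +
                ((g$j - dims[2] / 2) / (dims[2] / 3))^2 +
                ((g$k - dims[3] / 2) / (dims[3] / 2))^2))
  arr <- array(peak, dims) * (1 + 0.15 * (arr - min(arr)) / diff(range(arr)))
  arr / max(arr) * maxGy
}

# A reference/test dose pair with a smooth dose perturbation and a small
# spatial displacement of the test grid content.
gammaTestPair <- function(seed, dims = c(16L, 16L, 8L), spacing = c(3, 3, 3)) {
  ref <- smoothDoseField(dims, seed)
  set.seed(seed + 500)
  pert <- sctgan:::.gaussSmooth3(array(rnorm(prod(dims)), dims), rep(4, 3))
  pert <- 1 + 0.04 * pert / max(abs(pert))
  shift <- runif(3, -1.2, 1.2) * c(1, 1, 1)
  P <- sctgan:::.voxelCenters(dims, spacing, c(0, 0, 0))
  P <- sweep(P, 2, shift, "+")
  test <- array(sctgan:::.interp3(ref, spacing, c(0, 0, 0), P, clamp = TRUE),
                dims) * pert
  list(ref = doseGrid(ref, spacing), test = doseGrid(test, spacing))
}

# Brute-force directed/symmetric surface distances in plain R (all pairs).
# Explicit coordinate differences: the expanded |a|^2+|b|^2-2ab form loses
# ~1e-7 to cancellation near zero, too coarse for 1e-9 comparisons.
bruteSurfaceDists <- function(s1, s2) {
  nn <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i)
      sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 +
               (b[, 3] - a[i, 3])^2)), 0)
  }
  d12 <- nn(s1, s2); d21 <- nn(s2, s1)
  list(mda = (mean(d12) + mean(d21)) / 2, hd = max(max(d12), max(d21)))
}

# Direct SSIM of two equally sized patches (population statistics).
ssimOfPatches <- function(px, py, c1, c2) {
  n <- length(px)
  mx <- mean(px); my <- mean(py)
  vx <- mean(px^2) - mx^2; vy <- mean(py^2) - my^2
  cxy <- mean(px * py) - mx * my
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# SSIM map oracle: direct loop over pixels on an edge-inclusive mirror-padded
# image (independent of the integral-image path in the package).
ssimMapOracle <- function(x, y, cfg) {
  r <- (cfg@window - 1L) %/% 2L
  n1 <- nrow(x); n2 <- ncol(x)
  pi1 <- c(r:1, 1:n1, n1:(n1 - r + 1)); pi2 <- c(r:1, 1:n2, n2:(n2 - r + 1))
  xp <- x[pi1, pi2]; yp <- y[pi1, pi2]
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    px <- xp[i:(i + 2 * r), j:(j + 2 * r)]
    py <- yp[i:(i + 2 * r), j:(j + 2 * r)]
    out[i, j] <- ssimOfPatches(px, py, cfg@c1, cfg@c2)
  }
  out
}
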