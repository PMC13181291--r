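# Internal numerical helpers shared across modules.

# Physical centre coordinates (mm) of every voxel, as an N x 3 matrix in
# array order (first index fastest).
.voxelCenters <- function(dims, spacing, origin) {
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]), k = seq_len(dims[3]))
  cbind(origin[1] + (g$i - 1) * spacing[1],
        origin[2] + (g$j - 1) * spacing[2],
        origin[3] + (g$k - 1) * spacing[3])
}

# Trilinear interpolation of a 3D array at physical points P (N x 3, mm).
# Points outside the grid get `fill`, or the edge-clamped value if clamp=TRUE.
.interp3 <- function(arr, spacing, origin, P, fill = 0, clamp = FALSE) {
  d <- dim(arr)
  ci <- cbind((P[, 1] - origin[1]) / spacing[1] + 1,
              (P[, 2] - origin[2]) / spacing[2] + 1,
              (P[, 3] - origin[3]) / spacing[3] + 1)
  if (clamp) {
    for (a in 1:3) ci[, a] <- pmin(pmax(ci[, a], 1), d[a])
    inside <- rep(TRUE, nrow(ci))
  } else {
    # tolerate floating-point jitter at the support boundary
    tol <- 1e-9
    inside <- ci[, 1] >= 1 - tol & ci[, 1] <= d[1] + tol &
              ci[, 2] >= 1 - tol & ci[, 2] <= d[2] + tol &
              ci[, 3] >= 1 - tol & ci[, 3] <= d[3] + tol
  }
  out <- rep(as.numeric(fill), nrow(ci))
  if (!any(inside)) return(out)
  cii <- ci[inside, , drop = FALSE]
  if (!clamp) for (a in 1:3) cii[, a] <- pmin(pmax(cii[, a], 1), d[a])
  i0 <- pmin(floor(cii[, 1]), d[1] - 1L); fx <- cii[, 1] - i0
  j0 <- pmin(floor(cii[, 2]), d[2] - 1L); fy <- cii[, 2] - j0
  k0 <- pmin(floor(cii[, 3]), d[3] - 1L); fz <- cii[, 3] - k0
  if (d[1] == 1L) { i0 <- rep(1, nrow(cii)); fx <- rep(0, nrow(cii)) }
  if (d[2] == 1L) { j0 <- rep(1, nrow(cii)); fy <- rep(0, nrow(cii)) }
  if (d[3] == 1L) { k0 <- rep(1, nrow(cii)); fz <- rep(0, nrow(cii)) }
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (i0) + (j0 - 1) * n1 + (k0 - 1) * n12  # flat index of corner (i0,j0,k0)
  dx <- if (d[1] > 1L) 1L else 0L
  dy <- if (d[2] > 1L) n1 else 0L
  dz <- if (d[3] > 1L) n12 else 0L
  v <- arr[base]           * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[base + dx]      * fx       * (1 - fy) * (1 - fz) +
       arr[base + dy]      * (1 - fx) * fy       * (1 - fz) +
       arr[base + dx + dy] * fx       * fy       * (1 - fz) +
       arr[base + dz]           * (1 - fx) * (1 - fy) * fz +
       arr[base + dx + dz]      * fx       * (1 - fy) * fz +
       arr[base + dy + dz]      * (1 - fx) * fy       * fz +
       arr[base + dx + dy + dz] * fx       * fy       * fz
  out[inside] <- v
  out
}

# Shift a 3D logical array by integer offset (dx,dy,dz), filling with FALSE.
.shiftMask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { dst[[a]] <- seq_len(d[a] - o) + o; src[[a]] <- seq_len(d[a] - o) }
    else        { dst[[a]] <- seq_len(d[a] + o);     src[[a]] <- seq_len(d[a] + o) - o }
    if (length(src[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

.boxOffsets <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]   # 26 neighbours
})

.faceOffsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

# One-step binary dilation/erosion with the full 3x3x3 box structuring
# element; out-of-grid counts as background.
.dilate1 <- function(m) {
  out <- m
  for (r in seq_len(nrow(.boxOffsets)))
    out <- out | .shiftMask(m, .boxOffsets[r, ])
  out
}

.erode1 <- function(m) {
  out <- m
  for (r in seq_len(nrow(.boxOffsets)))
    out <- out & .shiftMask(m, .boxOffsets[r, ])
  out
}

# Separable Gaussian smoothing of a 3D array; sigma per axis in voxels.
# Edge-renormalized (kernel rows re-normalized where truncated by the border).
.gaussSmooth3 <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (a in 1:3) {
    s <- sigmaVox[a]
    if (s <= 0 || d[a] == 1L) next
    idx <- seq_len(d[a])
    K <- exp(-outer(idx, idx, "-")^2 / (2 * s^2))
    K <- K / rowSums(K)
    perm <- c(a, setdiff(1:3, a))
    m <- matrix(aperm(arr, perm), nrow = d[a])
    m <- K %*% m
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  arr
}

.stopifnotSameGrid <- function(d1, d2, what = "inputs") {
  if (!identical(as.integer(d1), as.integer(d2)))
    stop(what, " must share one grid (got ", paste(d1, collapse = "x"),
         " vs ", paste(d2, collapse = "x"), ")")
}
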