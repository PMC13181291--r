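# Contour agreement metrics: Dice similarity coefficient, mean distance to
# agreement and Hausdorff distance, with surface extraction in millimetre
# space. Surfaces are boundary-voxel centres under face (6-)connectivity;
# distance claims are therefore spacing-limited.

.asMask <- function(m) {
  if (is.logical(m)) return(m)
  if (!all(m %in% c(0, 1))) stop("mask must be strictly binary")
  array(m != 0, dim(m))
}

#' Dice similarity coefficient
#'
#' `2 |V1 n V2| / (|V1| + |V2|)`. Two empty masks are defined to agree
#' perfectly (DSC 1); silent sentinel values would hide upstream failures.
#'
#' @param v1,v2 binary masks on the same grid.
#' @return Scalar in `[0, 1]`.
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
#' dice(a, a)   # 1
#' @export
dice <- function(v1, v2) {
  v1 <- .asMask(v1); v2 <- .asMask(v2)
  .stopifnotSameGrid(dim(v1), dim(v2), "masks")
  n1 <- sum(v1); n2 <- sum(v2)
  if (n1 + n2 == 0L) return(1)
  2 * sum(v1 & v2) / (n1 + n2)
}

#' Extract surface points of a binary mask
#'
#' Returns the physical centres (mm) of mask voxels having at least one
#' face-adjacent background or out-of-grid neighbour.
#'
#' @param mask binary 3D mask.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) first voxel centre in mm.
#' @return `N x 3` matrix of surface point coordinates (mm).
#' @export
surfacePoints <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  mask <- .asMask(mask)
  if (!any(mask)) stop("surface of an empty mask is undefined")
  interior <- mask
  for (r in seq_len(nrow(.faceOffsets)))
    interior <- interior & .shiftMask(mask, .faceOffsets[r, ])
  surf <- mask & !interior
  idx <- which(surf, arr.ind = TRUE)
  cbind(origin[1] + (idx[, 1] - 1) * spacing[1],
        origin[2] + (idx[, 2] - 1) * spacing[2],
        origin[3] + (idx[, 3] - 1) * spacing[3])
}

.surfaceArgs <- function(s, spacing, origin) {
  if (is.matrix(s) && ncol(s) == 3L) return(s)
  surfacePoints(s, spacing, origin)
}

#' Mean distance to agreement (MDA)
#'
#' The symmetric average nearest-point distance between two surfaces:
#' `(dbar(S1 -> S2) + dbar(S2 -> S1)) / 2`, where `dbar` averages, over the
#' source points, the Euclidean distance to the closest target point.
#'
#' @param s1,s2 surfaces: `N x 3` point matrices from [surfacePoints()], or
#'   binary masks (converted using `spacing`/`origin`).
#' @param spacing,origin grid geometry used when masks are supplied.
#' @return MDA in mm.
#' @export
meanDistanceToAgreement <- function(s1, s2, spacing = c(1, 1, 1),
                                    origin = c(0, 0, 0)) {
  s1 <- .surfaceArgs(s1, spacing, origin)
  s2 <- .surfaceArgs(s2, spacing, origin)
  if (nrow(s1) == 0L || nrow(s2) == 0L) stop("empty surface point set")
  (mean(.cppNearestDist(s1, s2)) + mean(.cppNearestDist(s2, s1))) / 2
}

#' Hausdorff distance
#'
#' The maximum over both directions of the largest nearest-point distance
#' (100th percentile, not HD95).
#'
#' @inheritParams meanDistanceToAgreement
#' @return HD in mm.
#' @export
hausdorff <- function(s1, s2, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  s1 <- .surfaceArgs(s1, spacing, origin)
  s2 <- .surfaceArgs(s2, spacing, origin)
  if (nrow(s1) == 0L || nrow(s2) == 0L) stop("empty surface point set")
  max(max(.cppNearestDist(s1, s2)), max(.cppNearestDist(s2, s1)))
}

#' Contour metrics for every shared structure of two structure sets
#'
#' Computes DSC, MDA and HD per structure, with pass flags at the
#' commissioning tolerances DSC > 0.8 and MDA < 2 mm.
#'
#' @param ref,test [StructureSet-class] objects on the same grid.
#' @param dscTol,mdaTolMm tolerance flags (defaults 0.8 and 2 mm).
#' @return `data.frame` with one row per structure: `structure`, `dsc`,
#'   `mda_mm`, `hd_mm`, `dsc_pass`, `mda_pass`.
#' @export
contourMetrics <- function(ref, test, dscTol = 0.8, mdaTolMm = 2) {
  stopifnot(is(ref, "StructureSet"), is(test, "StructureSet"))
  .stopifnotSameGrid(ref@dim, test@dim, "structure sets")
  shared <- intersect(names(ref@masks), names(test@masks))
  if (!length(shared)) stop("no shared structure names")
  rows <- lapply(shared, function(nm) {
    m1 <- ref@masks[[nm]]; m2 <- test@masks[[nm]]
    d <- dice(m1, m2)
    s1 <- surfacePoints(m1, ref@spacing, ref@origin)
    s2 <- surfacePoints(m2, test@spacing, test@origin)
    mda <- meanDistanceToAgreement(s1, s2)
    hd <- hausdorff(s1, s2)
    data.frame(structure = nm, dsc = d, mda_mm = mda, hd_mm = hd,
               dsc_pass = d > dscTol, mda_pass = mda < mdaTolMm)
  })
  do.call(rbind, rows)
}
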