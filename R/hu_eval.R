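# CT-number fidelity: per-structure mean HU and differences, line profiles
# with Spearman rank correlation, and the HU -> relative electron density
# conversion.

#' Mean CT number within a structure
#'
#' @param vol an [ImageVolume-class].
#' @param mask binary mask on the volume's grid.
#' @return Mean HU over the mask voxels.
#' @export
meanHU <- function(vol, mask) {
  stopifnot(is(vol, "ImageVolume"))
  mask <- .asMask(mask)
  .stopifnotSameGrid(dim(vol@voxels), dim(mask), "volume and mask")
  if (!any(mask)) stop("mean HU of an empty mask is undefined")
  mean(vol@voxels[mask])
}

#' Per-structure mean CT-number differences
#'
#' For every structure, the difference of mean HU between a reference and a
#' test volume, with the reference-minus-test sign convention, plus the
#' absolute difference.
#'
#' @param ref,test [ImageVolume-class] objects on a shared grid.
#' @param structures a [StructureSet-class] on the same grid.
#' @return `data.frame`: `structure`, `mean_ref`, `mean_test`, `diff`
#'   (ref - test), `abs_diff`.
#' @export
huDifference <- function(ref, test, structures) {
  stopifnot(is(ref, "ImageVolume"), is(test, "ImageVolume"),
            is(structures, "StructureSet"))
  .stopifnotSameGrid(dim(ref@voxels), dim(test@voxels), "volumes")
  .stopifnotSameGrid(dim(ref@voxels), structures@dim, "volume and structures")
  rows <- lapply(names(structures@masks), function(nm) {
    m <- structures@masks[[nm]]
    a <- meanHU(ref, m); b <- meanHU(test, m)
    data.frame(structure = nm, mean_ref = a, mean_test = b, diff = a - b,
               abs_diff = abs(a - b))
  })
  do.call(rbind, rows)
}

#' CT-number line profile along a segment
#'
#' Samples the volume at `n` equidistant positions from `p0` to `p1`
#' (endpoints included) with trilinear interpolation.
#'
#' @param vol an [ImageVolume-class].
#' @param p0,p1 numeric(3) segment endpoints in mm; must lie inside the
#'   volume's voxel-centre extent.
#' @param n number of samples (>= 2).
#' @return `data.frame` with `position` (mm along the segment, starting at 0)
#'   and `hu`; endpoints attached as attributes `p0`, `p1`.
#' @export
lineProfile <- function(vol, p0, p1, n = 100L) {
  stopifnot(is(vol, "ImageVolume"), n >= 2L)
  d <- dim(vol@voxels)
  lo <- vol@origin; hi <- vol@origin + (d - 1) * vol@spacing
  for (p in list(p0, p1))
    if (any(p < lo - 1e-9) || any(p > hi + 1e-9))
      stop("profile segment exits the volume extent")
  len <- sqrt(sum((p1 - p0)^2))
  t <- seq(0, 1, length.out = n)
  P <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]),
             p0[3] + t * (p1[3] - p0[3]))
  hu <- .interp3(vol@voxels, vol@spacing, vol@origin, P, clamp = TRUE)
  out <- data.frame(position = t * len, hu = hu)
  attr(out, "p0") <- p0; attr(out, "p1") <- p1
  out
}

#' Spearman rank correlation of two profiles
#'
#' Pearson correlation of average-ranked values (ties averaged), via
#' [stats::cor()]. Constant input has no defined rank correlation and is an
#' error rather than `NA`.
#'
#' @param a,b numeric sequences of equal length >= 3.
#' @return Coefficient in `[-1, 1]`.
#' @export
spearmanRho <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("'a' and 'b' must have equal length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Spearman correlation is undefined for a constant sequence")
  stats::cor(a, b, method = "spearman")
}

#' Convert CT numbers to relative electron density
#'
#' Piecewise-linear interpolation between the curve knots, clamped to the end
#' knots outside the covered HU range.
#'
#' @param hu scalar or array of CT numbers.
#' @param curve a [REDCurve-class].
#' @return rED values with the shape of `hu`.
#' @examples
#' huToRED(-500, redCurve(c(-1000, 0), c(0, 1)))  # 0.5
#' @export
huToRED <- function(hu, curve = defaultREDCurve()) {
  stopifnot(is(curve, "REDCurve"))
  validObject(curve)
  out <- stats::approx(curve@hu, curve@red, xout = as.numeric(hu),
                       rule = 2)$y
  if (!is.null(dim(hu))) out <- array(out, dim(hu))
  out
}
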