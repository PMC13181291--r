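# Dose comparison: cumulative DVH, nearest-rank Dx% statistics, max point
# dose, and 3D global gamma analysis with a low-dose threshold.

#' Cumulative dose-volume histogram
#'
#' `V(d)` = percentage of mask voxels receiving at least dose `d`, evaluated
#' on a regular dose grid of the given bin width from 0 to just above the
#' maximum structure dose. `V(0) = 100` and the curve is nonincreasing.
#'
#' @param dose a [DoseGrid-class].
#' @param mask binary structure mask on the dose grid.
#' @param binWidthGy histogram bin width in Gy.
#' @return `data.frame` with `dose_gy` and `volume_pct`.
#' @export
cumulativeDVH <- function(dose, mask, binWidthGy = 0.1) {
  stopifnot(is(dose, "DoseGrid"), binWidthGy > 0)
  mask <- .asMask(mask)
  .stopifnotSameGrid(dim(dose@dose), dim(mask), "dose and mask")
  if (!any(mask)) stop("DVH of an empty mask is undefined")
  dm <- dose@dose[mask]
  bins <- seq(0, max(dm) + binWidthGy, by = binWidthGy)
  vol <- vapply(bins, function(d) 100 * mean(dm >= d), 0)
  data.frame(dose_gy = bins, volume_pct = vol)
}

#' Dose covering x percent of a structure (Dx%)
#'
#' Nearest-rank convention: structure doses are sorted in descending order
#' and the value at rank `ceiling(x/100 * N)` is returned — the dose received
#' by at least x% of the volume. (D2% is thus a near-maximum and D98% a
#' near-minimum dose.)
#'
#' @param dose a [DoseGrid-class].
#' @param mask binary structure mask.
#' @param xPercent volume percentage in `(0, 100]`.
#' @return Dose in Gy.
#' @export
doseAtVolume <- function(dose, mask, xPercent) {
  stopifnot(is(dose, "DoseGrid"), xPercent > 0, xPercent <= 100)
  mask <- .asMask(mask)
  .stopifnotSameGrid(dim(dose@dose), dim(mask), "dose and mask")
  if (!any(mask)) stop("Dx% of an empty mask is undefined")
  dm <- sort(dose@dose[mask], decreasing = TRUE)
  dm[ceiling(xPercent / 100 * length(dm))]
}

#' DVH statistics comparing a reference and a test dose
#'
#' D2%, D50% and D98% over the target mask for both grids, the global
#' maximum point dose, and their differences with the reference-minus-test
#' sign convention, both absolute (Gy) and relative (% of the reference
#' value).
#'
#' @param ref,test [DoseGrid-class] objects on a shared grid.
#' @param gtv binary target mask.
#' @return `data.frame` with one row per metric (`d2`, `d50`, `d98`,
#'   `max_point`): `ref_gy`, `test_gy`, `diff_gy`, `rel_diff_pct`.
#' @export
doseStats <- function(ref, test, gtv) {
  stopifnot(is(ref, "DoseGrid"), is(test, "DoseGrid"))
  .stopifnotSameGrid(dim(ref@dose), dim(test@dose), "dose grids")
  gtv <- .asMask(gtv)
  rows <- lapply(list(c("d2", 2), c("d50", 50), c("d98", 98)), function(m) {
    a <- doseAtVolume(ref, gtv, as.numeric(m[2]))
    b <- doseAtVolume(test, gtv, as.numeric(m[2]))
    data.frame(metric = m[1], ref_gy = a, test_gy = b, diff_gy = a - b,
               rel_diff_pct = if (a != 0) 100 * (a - b) / a else NA_real_)
  })
  a <- max(ref@dose); b <- max(test@dose)
  rows[[4]] <- data.frame(metric = "max_point", ref_gy = a, test_gy = b,
                          diff_gy = a - b,
                          rel_diff_pct = if (a != 0) 100 * (a - b) / a else NA_real_)
  do.call(rbind, rows)
}

# Shared setup for gamma computations: evaluated voxels and absolute
# tolerances. Pass criterion gamma <= 1 is applied with a 1e-9 numerical
# slack so exact-boundary constructions (dose difference exactly at
# tolerance) are not failed by floating-point rounding.
.gammaSetup <- function(ref, test, crit) {
  stopifnot(is(ref, "DoseGrid"), is(test, "DoseGrid"), is(crit, "GammaCriteria"))
  refMax <- max(ref@dose)
  if (refMax <= 0) stop("reference dose maximum must be > 0")
  thr <- crit@lowDoseThresholdPercent / 100 * refMax
  evalMask <- ref@dose >= thr
  if (!any(evalMask))
    stop("no voxels at or above the low-dose threshold: empty gamma evaluation")
  idx <- which(evalMask, arr.ind = TRUE)
  pos <- cbind(ref@origin[1] + (idx[, 1] - 1) * ref@spacing[1],
               ref@origin[2] + (idx[, 2] - 1) * ref@spacing[2],
               ref@origin[3] + (idx[, 3] - 1) * ref@spacing[3])
  list(refMax = refMax, evalMask = evalMask, pos = pos,
       refVal = ref@dose[evalMask],
       doseTol = crit@dosePercent / 100 * refMax,
       radius = crit@searchRadiusFactor * crit@dtaMm,
       step = crit@stepFraction * crit@dtaMm)
}

#' 3D global gamma map
#'
#' For every reference voxel with dose at or above the low-dose threshold,
#' the gamma index
#' `min over r of sqrt((D_test(r) - D_ref(r0))^2 / tol^2 + |r - r0|^2 / dta^2)`
#' is found by dense search within `searchRadiusFactor * dta` of the voxel at
#' step `stepFraction * dta`, with trilinear interpolation of the test dose
#' (which may live on a different grid in the same physical space). The dose
#' tolerance is global: `dosePercent` of the reference maximum. A voxel
#' passes when gamma <= 1 (with 1e-9 numerical slack).
#'
#' @param ref,test [DoseGrid-class] objects sharing a physical space.
#' @param crit a [GammaCriteria-class].
#' @return `list(gamma = array with NA outside the threshold mask,
#'   evalMask = logical array, passRate = percent of evaluated voxels
#'   passing, evaluated = number of evaluated voxels)`.
#' @export
gammaMap <- function(ref, test, crit) {
  g <- .gammaSetup(ref, test, crit)
  gv <- .cppGamma(g$pos, g$refVal, as.numeric(test@dose), dim(test@dose),
                  test@spacing, test@origin, g$doseTol, crit@dtaMm,
                  g$radius, g$step)
  gamma <- array(NA_real_, dim(ref@dose))
  gamma[g$evalMask] <- gv
  ok <- !is.na(gv)
  list(gamma = gamma, evalMask = g$evalMask,
       passRate = 100 * sum(gv[ok] <= 1 + 1e-9) / length(gv),
       evaluated = length(gv))
}

# Exhaustive-search reference implementation (finer default step); used as
# an independent cross-check of gammaMap.
.gammaOracle <- function(ref, test, crit, step = crit@stepFraction * crit@dtaMm / 2) {
  g <- .gammaSetup(ref, test, crit)
  gv <- .cppGammaOracle(g$pos, g$refVal, as.numeric(test@dose), dim(test@dose),
                        test@spacing, test@origin, g$doseTol, crit@dtaMm,
                        g$radius, step)
  ok <- !is.na(gv)
  list(gamma = gv, passRate = 100 * sum(gv[ok] <= 1 + 1e-9) / length(gv),
       evaluated = length(gv))
}

#' Gamma pass rates for a list of criteria
#'
#' @param ref,test [DoseGrid-class] objects.
#' @param criteria nonempty list of [GammaCriteria-class] objects.
#' @return `data.frame`: `dose_percent`, `dta_mm`, `pass_rate_pct`,
#'   `evaluated`.
#' @export
gammaSummary <- function(ref, test, criteria) {
  if (!is.list(criteria) || length(criteria) < 1L)
    stop("at least one gamma criteria set is required")
  rows <- lapply(criteria, function(cr) {
    r <- gammaMap(ref, test, cr)
    data.frame(dose_percent = cr@dosePercent, dta_mm = cr@dtaMm,
               pass_rate_pct = r$passRate, evaluated = r$evaluated)
  })
  do.call(rbind, rows)
}

#' The three clinical criteria sets used for sCT dose commissioning
#'
#' 3%/3mm, 2%/2mm and 1%/2mm, each with the 10% low-dose threshold.
#' @return List of [GammaCriteria-class] objects.
#' @export
clinicalGammaCriteria <- function() {
  list(gammaCriteria(3, 3), gammaCriteria(2, 2), gammaCriteria(1, 2))
}
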