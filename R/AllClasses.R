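#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib sctgan, .registration = TRUE
NULL

.HU_MIN <- -1024
.HU_MAX <- 3071

.check_geom <- function(spacing, origin) {
  msg <- character()
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || !all(is.finite(origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  msg
}

# ---------------------------------------------------------------------------
# ImageVolume
# ---------------------------------------------------------------------------

#' ImageVolume: a 3D HU-valued image on a regular grid
#'
#' The common currency of CT, CBCT and synthetic CT in this package: a 3D
#' array of Hounsfield units together with voxel spacing and origin in mm.
#' Voxel `[i,j,k]` has physical centre `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @slot voxels 3D numeric array of HU in `[-1024, 3071]`.
#' @slot spacing numeric(3), strictly positive voxel spacing in mm.
#' @slot origin numeric(3), physical position (mm) of the centre of voxel
#'   `[1,1,1]`.
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"))

setValidity("ImageVolume", function(object) {
  msg <- .check_geom(object@spacing, object@origin)
  v <- object@voxels
  if (length(dim(v)) != 3L)
    msg <- c(msg, "'voxels' must be a 3D array")
  else {
    if (!all(is.finite(v)))
      msg <- c(msg, "'voxels' must be finite")
    else {
      r <- range(v)
      if (r[1] < .HU_MIN || r[2] > .HU_MAX)
        msg <- c(msg, sprintf("HU values must lie in [%d, %d] (found [%.1f, %.1f])",
                              .HU_MIN, .HU_MAX, r[1], r[2]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array of HU.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) position of the first voxel centre in mm.
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- imageVolume(array(0, c(8, 8, 4)), spacing = c(1, 1, 2))
#' spacing(vol)
#' @export
imageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# ---------------------------------------------------------------------------
# StructureSet
# ---------------------------------------------------------------------------

#' StructureSet: named binary masks on a shared grid
#'
#' Holds segmentation masks (reference or auto/perturbed contours) as named
#' logical arrays, all aligned to one reference grid.
#'
#' @slot masks named list of 3D logical arrays, all of identical dimension.
#' @slot dim integer(3) reference grid dimension.
#' @slot spacing numeric(3) voxel spacing (mm).
#' @slot origin numeric(3) first voxel centre (mm).
#' @export
setClass("StructureSet",
  representation(masks = "list", dim = "integer", spacing = "numeric",
                 origin = "numeric"))

setValidity("StructureSet", function(object) {
  msg <- .check_geom(object@spacing, object@origin)
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "'dim' must be 3 positive integers")
  if (length(object@masks)) {
    if (is.null(names(object@masks)) || any(!nzchar(names(object@masks))))
      msg <- c(msg, "all masks must be named")
    for (nm in names(object@masks)) {
      m <- object@masks[[nm]]
      if (!is.logical(m) || !identical(dim(m), object@dim))
        msg <- c(msg, sprintf("mask '%s' must be a logical array matching dim", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StructureSet
#'
#' @param masks named list of 3D masks (logical, or numeric in \{0,1\}).
#' @param spacing,origin grid geometry in mm.
#' @return A [StructureSet-class] object.
#' @export
structureSet <- function(masks, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  masks <- lapply(masks, function(m) {
    if (!is.logical(m)) {
      if (!all(m %in% c(0, 1))) stop("masks must be strictly binary")
      m <- array(m != 0, dim(m))
    }
    m
  })
  new("StructureSet", masks = masks, dim = dim(masks[[1L]]),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

# ---------------------------------------------------------------------------
# DoseGrid
# ---------------------------------------------------------------------------

#' DoseGrid: a 3D dose distribution in Gy
#'
#' @slot dose 3D numeric array of nonnegative dose values (Gy).
#' @slot spacing numeric(3) voxel spacing (mm).
#' @slot origin numeric(3) first voxel centre (mm).
#' @export
setClass("DoseGrid",
  representation(dose = "array", spacing = "numeric", origin = "numeric"))

setValidity("DoseGrid", function(object) {
  msg <- .check_geom(object@spacing, object@origin)
  d <- object@dose
  if (length(dim(d)) != 3L)
    msg <- c(msg, "'dose' must be a 3D array")
  else if (!all(is.finite(d)) || any(d < 0))
    msg <- c(msg, "'dose' must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseGrid
#'
#' @param dose 3D numeric array of dose (Gy), nonnegative.
#' @param spacing,origin grid geometry in mm.
#' @return A [DoseGrid-class] object.
#' @export
doseGrid <- function(dose, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("DoseGrid", dose = dose, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# ---------------------------------------------------------------------------
# GammaCriteria
# ---------------------------------------------------------------------------

#' GammaCriteria: parameters of a 3D global gamma comparison
#'
#' The dose-difference / distance-to-agreement criterion pair, the low-dose
#' threshold, and the numerical search parameters. The dose tolerance is
#' global: `dosePercent` percent of the reference-dose maximum.
#'
#' @slot dosePercent dose-difference criterion, percent of reference maximum.
#' @slot dtaMm distance-to-agreement criterion in mm.
#' @slot lowDoseThresholdPercent voxels with reference dose below this percent
#'   of the reference maximum are excluded from evaluation (default 10).
#' @slot searchRadiusFactor spatial search radius as a multiple of `dtaMm`.
#' @slot stepFraction search sampling step as a fraction of `dtaMm`.
#' @export
setClass("GammaCriteria",
  representation(dosePercent = "numeric", dtaMm = "numeric",
                 lowDoseThresholdPercent = "numeric",
                 searchRadiusFactor = "numeric", stepFraction = "numeric"))

setValidity("GammaCriteria", function(object) {
  vals <- c(object@dosePercent, object@dtaMm, object@lowDoseThresholdPercent,
            object@searchRadiusFactor, object@stepFraction)
  msg <- character()
  if (length(vals) != 5L || !all(is.finite(vals)) || any(vals <= 0))
    msg <- c(msg, "all gamma criteria parameters must be strictly positive scalars")
  else if (object@stepFraction > 1)
    msg <- c(msg, "'stepFraction' must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Construct gamma criteria
#'
#' @param dosePercent global dose-difference tolerance (% of reference max).
#' @param dtaMm distance-to-agreement tolerance (mm).
#' @param lowDoseThresholdPercent low-dose exclusion threshold (% of
#'   reference max); the conventional commissioning default is 10.
#' @param searchRadiusFactor,stepFraction numerical search parameters.
#' @return A [GammaCriteria-class] object.
#' @examples
#' gammaCriteria(3, 3)   # 3%/3mm
#' gammaCriteria(1, 2)   # 1%/2mm
#' @export
gammaCriteria <- function(dosePercent, dtaMm, lowDoseThresholdPercent = 10,
                          searchRadiusFactor = 2, stepFraction = 0.1) {
  new("GammaCriteria", dosePercent = dosePercent, dtaMm = dtaMm,
      lowDoseThresholdPercent = lowDoseThresholdPercent,
      searchRadiusFactor = searchRadiusFactor, stepFraction = stepFraction)
}

# ---------------------------------------------------------------------------
# REDCurve
# ---------------------------------------------------------------------------

#' REDCurve: HU to relative electron density conversion curve
#'
#' Ordered knots mapping CT number to relative electron density (rED),
#' interpolated piecewise-linearly and clamped to the end knots.
#'
#' @slot hu numeric, strictly increasing knot positions in HU.
#' @slot red numeric, nondecreasing nonnegative rED values at the knots.
#' @export
setClass("REDCurve", representation(hu = "numeric", red = "numeric"))

setValidity("REDCurve", function(object) {
  msg <- character()
  if (length(object@hu) < 2L || length(object@hu) != length(object@red))
    msg <- c(msg, "curve needs >= 2 (hu, red) knots of equal length")
  else {
    if (any(diff(object@hu) <= 0)) msg <- c(msg, "'hu' knots must be strictly increasing")
    if (any(diff(object@red) < 0)) msg <- c(msg, "'red' must be nondecreasing")
    if (any(object@red < 0)) msg <- c(msg, "'red' must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an HU to rED conversion curve
#'
#' @param hu strictly increasing knot CT numbers.
#' @param red nondecreasing relative electron densities at the knots.
#' @return A [REDCurve-class] object.
#' @export
redCurve <- function(hu, red) new("REDCurve", hu = as.numeric(hu), red = as.numeric(red))

#' Default water-anchored rED curve
#'
#' Three knots: air (-1000 HU, rED 0), water (0 HU, rED 1) and dense bone
#' (2000 HU, rED 2.2). Clinical curves are scanner-specific; this anchored
#' default is adequate for the analytic phantom beams.
#'
#' @return A [REDCurve-class] object.
#' @export
defaultREDCurve <- function() redCurve(c(-1000, 0, 2000), c(0, 1, 2.2))

# ---------------------------------------------------------------------------
# LossConfig
# ---------------------------------------------------------------------------

#' LossConfig: parameters of the SSIM-weighted cycleGAN loss
#'
#' @slot alpha SSIM threshold in `[0,1]`; local SSIM below `alpha` gives a
#'   zero L1 weight (default 0.5).
#' @slot window odd SSIM patch side in pixels (default 7).
#' @slot c1,c2 SSIM stability constants (defaults `(0.01*L)^2`, `(0.03*L)^2`
#'   with dynamic range `L = 2` on the normalized `[-1,1]` intensity scale).
#' @slot lambdaCycle,lambdaSSIM,lambdaAdv nonnegative term weights.
#' @export
setClass("LossConfig",
  representation(alpha = "numeric", window = "integer", c1 = "numeric",
                 c2 = "numeric", lambdaCycle = "numeric", lambdaSSIM = "numeric",
                 lambdaAdv = "numeric"))

setValidity("LossConfig", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "'alpha' must be in [0,1]")
  if (object@window < 3L || object@window %% 2L == 0L)
    msg <- c(msg, "'window' must be odd and >= 3")
  if (object@c1 <= 0 || object@c2 <= 0) msg <- c(msg, "'c1','c2' must be > 0")
  lam <- c(object@lambdaCycle, object@lambdaSSIM, object@lambdaAdv)
  if (!all(is.finite(lam)) || any(lam < 0)) msg <- c(msg, "lambdas must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a loss configuration
#'
#' @param alpha SSIM threshold (default 0.5).
#' @param window odd SSIM patch side (default 7).
#' @param c1,c2 SSIM stability constants on the `[-1,1]` scale.
#' @param lambdaCycle,lambdaSSIM,lambdaAdv term weights (cycleGAN-convention
#'   defaults 10, 10, 1).
#' @return A [LossConfig-class] object.
#' @export
lossConfig <- function(alpha = 0.5, window = 7L, c1 = (0.01 * 2)^2,
                       c2 = (0.03 * 2)^2, lambdaCycle = 10, lambdaSSIM = 10,
                       lambdaAdv = 1) {
  new("LossConfig", alpha = alpha, window = as.integer(window), c1 = c1, c2 = c2,
      lambdaCycle = lambdaCycle, lambdaSSIM = lambdaSSIM, lambdaAdv = lambdaAdv)
}

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume %dx%dx%d @ (%.3g, %.3g, %.3g) mm  HU [%.0f, %.0f]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], min(object@voxels), max(object@voxels)))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet on %dx%dx%d grid @ (%.3g, %.3g, %.3g) mm\n",
              object@dim[1], object@dim[2], object@dim[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  for (nm in names(object@masks))
    cat(sprintf("  %-14s %d voxels\n", nm, sum(object@masks[[nm]])))
})

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@dose)
  cat(sprintf("DoseGrid %dx%dx%d @ (%.3g, %.3g, %.3g) mm  max %.3g Gy\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], max(object@dose)))
})

setMethod("show", "GammaCriteria", function(object) {
  cat(sprintf("GammaCriteria %g%%/%gmm (threshold %g%%)\n", object@dosePercent,
              object@dtaMm, object@lowDoseThresholdPercent))
})

setMethod("show", "REDCurve", function(object) {
  cat(sprintf("REDCurve with %d knots: HU [%g, %g] -> rED [%g, %g]\n",
              length(object@hu), min(object@hu), max(object@hu),
              min(object@red), max(object@red)))
})

setMethod("show", "LossConfig", function(object) {
  cat(sprintf(
    "LossConfig alpha=%g window=%d lambdas (cycle, ssim, adv) = (%g, %g, %g)\n",
    object@alpha, object@window, object@lambdaCycle, object@lambdaSSIM,
    object@lambdaAdv))
})
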