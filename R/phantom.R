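# Digital pelvis phantom: seeded generator of paired CT / CBCT volumes, a
# deformably "registered" CT carrying a local structural mismatch, structure
# masks, perturbed contours, and analytic pencil-beam dose grids. The anatomy
# is an ellipsoid composite; only its statistical contrast structure matters
# for exercising the translation model and the evaluation metrics.

#' PhantomSpec: configuration of the digital pelvis phantom
#'
#' @slot dim integer(3) grid dimension (default 64 x 64 x 16).
#' @slot spacing numeric(3) voxel spacing mm (default 3 mm isotropic).
#' @slot origin numeric(3) first voxel centre (mm).
#' @slot structures named list; each element has `center` (mm), `radii` (mm),
#'   `hu` (mean), `sd` (HU noise sigma), `priority` (higher paints over lower;
#'   equal-priority overlaps are an error), optional `parent` (inherit the
#'   parent's centre jitter so contained structures stay contained).
#' @slot centerJitterMM,radiiJitterFrac seeded per-phantom anatomical
#'   variability applied by [makePhantomCT()].
#' @slot cuppingHU radial cupping amplitude (HU) of the CBCT bias field.
#' @slot noiseSD additive CBCT Gaussian noise sigma (HU).
#' @slot streakCount,streakIntensity number and amplitude (HU) of streaks
#'   emanating from gas voxels.
#' @slot huShift global CBCT HU shift.
#' @slot maxDisplacementMM bound on the residual deformation of the
#'   registered CT (max vector norm of the displacement field).
#' @slot deformSigmaMM Gaussian smoothness of the displacement field.
#' @slot mismatchStructure name of the structure present in the CBCT but
#'   replaced by surrounding tissue in the registered CT (`NA` for none).
#' @slot beams list of beams, each `list(angleDeg, widthMM, entranceDose, mu)`
#'   (width = lateral FWHM in mm, mu = attenuation coefficient per mm).
#' @slot doseStepMM ray-marching step of the analytic dose model (mm).
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric", origin = "numeric",
                 structures = "list", centerJitterMM = "numeric",
                 radiiJitterFrac = "numeric", cuppingHU = "numeric",
                 noiseSD = "numeric", streakCount = "integer",
                 streakIntensity = "numeric", huShift = "numeric",
                 maxDisplacementMM = "numeric", deformSigmaMM = "numeric",
                 mismatchStructure = "character", beams = "list",
                 doseStepMM = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- .check_geom(object@spacing, object@origin)
  if (length(object@dim) != 3L || any(object@dim < 4L))
    msg <- c(msg, "'dim' must be 3 integers >= 4")
  for (nm in names(object@structures)) {
    s <- object@structures[[nm]]
    if (!all(c("center", "radii", "hu", "sd", "priority") %in% names(s)))
      msg <- c(msg, sprintf("structure '%s' incomplete", nm))
    else {
      if (s$sd < 0) msg <- c(msg, sprintf("structure '%s': sd must be >= 0", nm))
      if (s$hu < .HU_MIN || s$hu > .HU_MAX)
        msg <- c(msg, sprintf("structure '%s': mean HU outside [%d, %d]",
                              nm, .HU_MIN, .HU_MAX))
      if (any(s$radii <= 0)) msg <- c(msg, sprintf("structure '%s': radii must be > 0", nm))
    }
  }
  if (object@noiseSD < 0) msg <- c(msg, "'noiseSD' must be >= 0")
  if (object@maxDisplacementMM < 0) msg <- c(msg, "'maxDisplacementMM' must be >= 0")
  if (!is.na(object@mismatchStructure) &&
      !object@mismatchStructure %in% names(object@structures))
    msg <- c(msg, "'mismatchStructure' not among structures")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %dx%dx%d @ (%g, %g, %g) mm, %d structures, %d beams\n",
              object@dim[1], object@dim[2], object@dim[3], object@spacing[1],
              object@spacing[2], object@spacing[3], length(object@structures),
              length(object@beams)))
})

.defaultStructures <- function() {
  # Pelvis-like ellipsoid composite on a 192 x 192 x 48 mm extent. Gaps
  # between equal-priority structures exceed the worst-case anatomical
  # jitter so seeded cohorts never trip the overlap check.
  list(
    body        = list(center = c(96, 96, 24),  radii = c(86, 74, 90),
                       hu = 30,   sd = 15, priority = 0),
    bladder     = list(center = c(96, 58, 24),  radii = c(22, 16, 26),
                       hu = 10,   sd = 8,  priority = 1),
    prostate    = list(center = c(96, 96, 24),  radii = c(15, 12, 22),
                       hu = 45,   sd = 10, priority = 1),
    rectum      = list(center = c(96, 130, 24), radii = c(13, 11, 40),
                       hu = 20,   sd = 10, priority = 1),
    rectal_gas  = list(center = c(96, 130, 26), radii = c(9, 9, 8),
                       hu = -800, sd = 30, priority = 2, parent = "rectum"),
    femur_left  = list(center = c(32, 96, 24),  radii = c(14, 14, 44),
                       hu = 400,  sd = 60, priority = 1),
    femur_right = list(center = c(160, 96, 24), radii = c(14, 14, 44),
                       hu = 400,  sd = 60, priority = 1),
    sacrum      = list(center = c(96, 160, 24), radii = c(18, 10, 44),
                       hu = 300,  sd = 50, priority = 1))
}

.defaultBeams <- function() {
  # Four-field box, prostate-directed; mu ~ water at MV energies (per mm).
  list(list(angleDeg = 0,   widthMM = 60, entranceDose = 20, mu = 0.005),
       list(angleDeg = 90,  widthMM = 60, entranceDose = 20, mu = 0.005),
       list(angleDeg = 180, widthMM = 60, entranceDose = 20, mu = 0.005),
       list(angleDeg = 270, widthMM = 60, entranceDose = 20, mu = 0.005))
}

#' Construct a phantom specification
#'
#' Defaults define a 64 x 64 x 16 voxel, 3 mm isotropic pelvis-like phantom
#' with body, bladder, prostate, rectum (with a gas pocket), femoral heads and
#' sacrum, moderate CBCT artifact strengths, a bounded residual deformation
#' for the registered CT with the gas pocket as mismatch structure, and a
#' four-field prostate beam arrangement.
#'
#' @param dim,spacing,origin grid geometry.
#' @param structures structure list; see [PhantomSpec-class].
#' @param centerJitterMM,radiiJitterFrac seeded anatomical variability.
#' @param cuppingHU,noiseSD,streakCount,streakIntensity,huShift CBCT artifact
#'   strengths (all zero reproduces the CT exactly).
#' @param maxDisplacementMM,deformSigmaMM registered-CT deformation.
#' @param mismatchStructure structure simulated as present in the CBCT but
#'   absent from the registered CT (`NA_character_` disables).
#' @param beams analytic beam list; see [PhantomSpec-class].
#' @param doseStepMM ray-marching step (mm).
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(dim = c(64L, 64L, 16L), spacing = c(3, 3, 3),
                        origin = c(0, 0, 0), structures = .defaultStructures(),
                        centerJitterMM = 3, radiiJitterFrac = 0.06,
                        cuppingHU = 60, noiseSD = 20, streakCount = 8L,
                        streakIntensity = 60, huShift = -30,
                        maxDisplacementMM = 4, deformSigmaMM = 9,
                        mismatchStructure = "rectal_gas",
                        beams = .defaultBeams(), doseStepMM = 2) {
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      origin = as.numeric(origin), structures = structures,
      centerJitterMM = centerJitterMM, radiiJitterFrac = radiiJitterFrac,
      cuppingHU = cuppingHU, noiseSD = noiseSD,
      streakCount = as.integer(streakCount), streakIntensity = streakIntensity,
      huShift = huShift, maxDisplacementMM = maxDisplacementMM,
      deformSigmaMM = deformSigmaMM, mismatchStructure = mismatchStructure,
      beams = beams, doseStepMM = doseStepMM)
}

.ellipsoidMask <- function(dims, spacing, origin, center, radii) {
  x <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  z <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  ux <- ((x - center[1]) / radii[1])^2
  uy <- ((y - center[2]) / radii[2])^2
  uz <- ((z - center[3]) / radii[3])^2
  array(outer(outer(ux, uy, "+"), uz, "+") <= 1, dims)
}

#' Generate the phantom CT and its structure masks
#'
#' Paints ellipsoidal structures in priority order onto an air background,
#' adds per-structure Gaussian HU texture, and applies a seeded anatomical
#' jitter to centres and radii. Organ masks are clipped to the body and to
#' priority (a voxel belongs to the highest-priority structure covering it);
#' the body mask is the full body ellipsoid, so every organ mask is contained
#' in it. Deterministic given `(spec, seed)`.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer RNG seed.
#' @return `list(ct = ImageVolume, structures = StructureSet)`.
#' @examples
#' ph <- makePhantomCT(phantomSpec(), seed = 1)
#' ph$ct
#' @export
makePhantomCT <- function(spec, seed) {
  validObject(spec)
  set.seed(seed)
  dims <- spec@dim; sp <- spec@spacing; or <- spec@origin
  strs <- spec@structures
  # seeded anatomical jitter; children inherit the parent's centre jitter
  jit <- list()
  for (nm in names(strs)) {
    jit[[nm]] <- list(dc = stats::runif(3, -spec@centerJitterMM, spec@centerJitterMM),
                      fr = stats::runif(1, 1 - spec@radiiJitterFrac,
                                        1 + spec@radiiJitterFrac))
  }
  for (nm in names(strs)) {
    p <- strs[[nm]]$parent
    if (!is.null(p)) jit[[nm]]$dc <- jit[[p]]$dc
    strs[[nm]]$center <- strs[[nm]]$center + jit[[nm]]$dc
    strs[[nm]]$radii <- strs[[nm]]$radii * jit[[nm]]$fr
  }
  inside <- lapply(strs, function(s)
    .ellipsoidMask(dims, sp, or, s$center, s$radii))
  if (!"body" %in% names(strs)) stop("spec must contain a 'body' structure")
  body <- inside[["body"]]
  prio <- vapply(strs, function(s) as.numeric(s$priority), 0)
  # equal-priority overlap is unresolved -> error naming the pair
  nms <- names(strs)
  for (i in seq_along(nms)) for (j in seq_len(i - 1L)) {
    if (prio[i] == prio[j] && any(inside[[i]] & inside[[j]]))
      stop("overlapping structures with equal priority: '", nms[j],
           "' and '", nms[i], "'")
  }
  hu <- array(-1000, dims)
  sdArr <- array(0, dims)
  for (nm in nms[order(prio)]) {
    reg <- inside[[nm]] & body
    hu[reg] <- strs[[nm]]$hu
    sdArr[reg] <- strs[[nm]]$sd
  }
  noisy <- sdArr > 0
  hu[noisy] <- hu[noisy] + stats::rnorm(sum(noisy), 0, sdArr[noisy])
  hu <- pmin(pmax(hu, .HU_MIN), .HU_MAX)
  maskList <- list()
  for (nm in nms) {
    if (nm == "body") { maskList[[nm]] <- body; next }
    m <- inside[[nm]] & body
    for (other in nms[prio > prio[nm]]) m <- m & !inside[[other]]
    maskList[[nm]] <- m
  }
  list(ct = imageVolume(array(hu, dims), sp, or),
       structures = structureSet(maskList, sp, or))
}

#' Degrade a CT volume into a CBCT-like volume
#'
#' Applies, in order: a radial cupping bias field
#' `delta(r) = -A * (1 - r^2 / Rmax^2)` (`r` = in-plane distance from the grid
#' centre, `Rmax` = in-plane half-diagonal, so the centre is depressed by `A`
#' HU and the edge untouched); additive Gaussian HU noise; streaks emanating
#' from gas voxels (HU < -400) at random in-plane angles with exponentially
#' decaying amplitude (60 mm decay length, alternating sign); and a global HU
#' shift. All-zero strengths reproduce the input exactly.
#'
#' @param ct an [ImageVolume-class].
#' @param spec a [PhantomSpec-class] carrying the artifact strengths.
#' @param seed integer RNG seed.
#' @return An [ImageVolume-class].
#' @export
degradeToCBCT <- function(ct, spec, seed) {
  stopifnot(is(ct, "ImageVolume"), is(spec, "PhantomSpec"))
  set.seed(seed)
  dims <- dim(ct@voxels); sp <- ct@spacing; or <- ct@origin
  v <- ct@voxels
  if (spec@cuppingHU != 0)
    v <- v + cuppingField(dims, sp, or, spec@cuppingHU)
  if (spec@noiseSD > 0)
    v <- v + array(stats::rnorm(prod(dims), 0, spec@noiseSD), dims)
  if (spec@streakCount > 0L && spec@streakIntensity != 0) {
    gas <- which(ct@voxels < -400)
    if (length(gas)) {
      delta <- array(0, dims)
      idx <- arrayInd(gas, dims)
      for (s in seq_len(spec@streakCount)) {
        g <- idx[sample.int(nrow(idx), 1L), ]
        gx <- or[1] + (g[1] - 1) * sp[1]
        gy <- or[2] + (g[2] - 1) * sp[2]
        phi <- stats::runif(1, 0, pi)
        L <- sqrt((dims[1] * sp[1])^2 + (dims[2] * sp[2])^2)
        t <- seq(-L, L, by = min(sp[1:2]) / 2)
        px <- round((gx + t * cos(phi) - or[1]) / sp[1]) + 1L
        py <- round((gy + t * sin(phi) - or[2]) / sp[2]) + 1L
        ok <- px >= 1L & px <= dims[1] & py >= 1L & py <= dims[2]
        amp <- spec@streakIntensity * exp(-abs(t) / 60) *
          (if (s %% 2L == 0L) -1 else 1)
        ordIdx <- order(abs(t[ok]))
        cell <- (px[ok] + (py[ok] - 1L) * dims[1])[ordIdx]
        ampo <- amp[ok][ordIdx]
        keep <- !duplicated(cell)
        sliceDelta <- delta[, , g[3]]
        sliceDelta[cell[keep]] <- sliceDelta[cell[keep]] + ampo[keep]
        delta[, , g[3]] <- sliceDelta
      }
      v <- v + delta
    }
  }
  if (spec@huShift != 0) v <- v + spec@huShift
  v <- pmin(pmax(v, .HU_MIN), .HU_MAX)
  imageVolume(array(v, dims), sp, or)
}

#' Analytic radial cupping bias field
#'
#' The closed-form field added by [degradeToCBCT()]:
#' `-A * (1 - r^2 / Rmax^2)` per voxel.
#'
#' @param dims,spacing,origin grid geometry.
#' @param amplitude cupping amplitude A in HU.
#' @return 3D array of HU offsets.
#' @export
cuppingField <- function(dims, spacing, origin, amplitude) {
  cx <- origin[1] + (dims[1] - 1) / 2 * spacing[1]
  cy <- origin[2] + (dims[2] - 1) / 2 * spacing[2]
  x <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  r2 <- outer((x - cx)^2, (y - cy)^2, "+")
  rmax2 <- (dims[1] * spacing[1] / 2)^2 + (dims[2] * spacing[2] / 2)^2
  slice <- -amplitude * (1 - r2 / rmax2)
  array(rep(slice, dims[3]), dims)
}

#' Produce a deformably "registered" CT with a local structural mismatch
#'
#' Warps the CT by a smooth random displacement field whose maximum vector
#' norm equals `maxDisplacementMM` (Gaussian-smoothed white noise, rescaled),
#' emulating residual post-registration error. If a mismatch structure is
#' requested, the corresponding CBCT region is replaced by surrounding-tissue
#' HU, so the registered CT lacks a structure the CBCT contains — the
#' scenario the SSIM-thresholded loss is designed to survive.
#'
#' @param ct an [ImageVolume-class] (the clean CT underlying the CBCT).
#' @param cbctStructures [StructureSet-class] with the CBCT-frame masks.
#' @param spec a [PhantomSpec-class].
#' @param seed integer RNG seed.
#' @return `list(registeredCT = ImageVolume, mismatchMask = logical array,
#'   displacement = 4D array [dim, 3] in mm)`.
#' @export
makeRegisteredCT <- function(ct, cbctStructures, spec, seed) {
  stopifnot(is(ct, "ImageVolume"), is(cbctStructures, "StructureSet"),
            is(spec, "PhantomSpec"))
  wantMismatch <- !is.na(spec@mismatchStructure)
  if (spec@maxDisplacementMM <= 0 && wantMismatch)
    stop("displacement bound must be > 0 when a mismatch structure is requested")
  set.seed(seed)
  dims <- dim(ct@voxels); sp <- ct@spacing; or <- ct@origin
  disp <- array(0, c(dims, 3L))
  v <- ct@voxels
  if (spec@maxDisplacementMM > 0) {
    sigmaVox <- spec@deformSigmaMM / sp
    for (a in 1:3)
      disp[, , , a] <- .gaussSmooth3(array(stats::rnorm(prod(dims)), dims), sigmaVox)
    nrm <- sqrt(disp[, , , 1]^2 + disp[, , , 2]^2 + disp[, , , 3]^2)
    mx <- max(nrm)
    if (mx > 0) disp <- disp * (spec@maxDisplacementMM / mx)
    P <- .voxelCenters(dims, sp, or) +
      cbind(as.vector(disp[, , , 1]), as.vector(disp[, , , 2]),
            as.vector(disp[, , , 3]))
    v <- array(.interp3(ct@voxels, sp, or, P, clamp = TRUE), dims)
  }
  mismatchMask <- array(FALSE, dims)
  if (wantMismatch) {
    region <- cbctStructures[[spec@mismatchStructure]]
    if (any(region)) {
      shell <- .dilate1(.dilate1(region)) & !region
      fill <- if (any(shell)) mean(v[shell]) else 0
      v[region] <- fill + stats::rnorm(sum(region), 0, 5)
      mismatchMask <- region
    }
  }
  v <- pmin(pmax(v, .HU_MIN), .HU_MAX)
  list(registeredCT = imageVolume(array(v, dims), sp, or),
       mismatchMask = mismatchMask, displacement = disp)
}

#' Analytic pencil-beam dose on a CT volume
#'
#' Each beam deposits `entranceDose * exp(-mu * radiologicalDepth) *
#' exp(-lateral^2 / (2 sigma^2))`, with sigma from the beam's lateral FWHM and
#' the radiological depth accumulated by midpoint ray marching of the relative
#' electron density (from [huToRED()]) along the beam axis; tissue outside the
#' grid contributes nothing. Beams lie in the axial plane; the axis passes
#' through the grid centre at the given gantry angle (0 deg travels +y,
#' 90 deg travels +x). Deterministic; dose is linear in `entranceDose`.
#'
#' @param ct an [ImageVolume-class].
#' @param spec a [PhantomSpec-class] carrying the beam list and march step.
#' @param curve a [REDCurve-class] for HU to rED conversion.
#' @return A [DoseGrid-class].
#' @export
makeDose <- function(ct, spec, curve = defaultREDCurve()) {
  stopifnot(is(ct, "ImageVolume"), is(spec, "PhantomSpec"), is(curve, "REDCurve"))
  if (length(spec@beams) < 1L) stop("at least one beam is required")
  dims <- dim(ct@voxels); sp <- ct@spacing; or <- ct@origin
  red <- array(huToRED(ct@voxels, curve), dims)
  P <- .voxelCenters(dims, sp, or)
  extent <- dims * sp
  iso <- or + (dims - 1) / 2 * sp
  lo <- or - sp / 2; hi <- or + (dims - 0.5) * sp
  step <- spec@doseStepMM
  Lmax <- sqrt(sum(extent^2))
  K <- ceiling(Lmax / step)
  dose <- numeric(nrow(P))
  for (b in spec@beams) {
    off <- if (!is.null(b$isoOffsetMM)) as.numeric(b$isoOffsetMM) else c(0, 0, 0)
    axis <- iso + off
    if (any(axis < lo) || any(axis > hi))
      stop("beam axis (isocentre) lies outside the grid")
    th <- b$angleDeg * pi / 180
    d <- c(sin(th), cos(th), 0)
    if (b$entranceDose == 0) next
    rel <- sweep(P, 2, axis)
    along <- rel %*% d
    lat2 <- rowSums(rel^2) - as.vector(along)^2
    lat2[lat2 < 0] <- 0
    sigma <- b$widthMM / (2 * sqrt(2 * log(2)))
    raddepth <- numeric(nrow(P))
    for (k in seq_len(K)) {
      s <- (k - 0.5) * step
      Q <- cbind(P[, 1] - d[1] * s, P[, 2] - d[2] * s, P[, 3] - d[3] * s)
      raddepth <- raddepth + .interp3(red, sp, or, Q, fill = 0) * step
    }
    dose <- dose + b$entranceDose * exp(-b$mu * raddepth) *
      exp(-lat2 / (2 * sigma^2))
  }
  doseGrid(array(dose, dims), sp, or)
}

#' Perturb a binary contour mask
#'
#' Fabricates "auto-segmented" counterparts of a reference contour for
#' exercising the agreement metrics. Modes: `dilate` / `erode` (full 3x3x3
#' box structuring element, `round(magnitude)` iterations), `boundary_noise`
#' (each inner/outer boundary voxel flipped with probability `magnitude`),
#' `shift` (translation by `magnitude` mm in a seeded random direction,
#' rounded to voxels). Magnitude 0 is the identity; deterministic given seed.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param mode one of `"dilate"`, `"erode"`, `"boundary_noise"`, `"shift"`.
#' @param magnitude nonnegative perturbation strength (see modes).
#' @param seed integer RNG seed (used by the stochastic modes).
#' @param spacing numeric(3) voxel spacing in mm (used by `shift`).
#' @return Perturbed logical mask of the same dimension.
#' @export
perturbContour <- function(mask, mode = c("dilate", "erode", "boundary_noise",
                                          "shift"),
                           magnitude, seed = 0L, spacing = c(1, 1, 1)) {
  if (is.character(mode) && length(mode) == 1L &&
      !mode %in% c("dilate", "erode", "boundary_noise", "shift"))
    stop("unknown perturbation mode '", mode, "'")
  mode <- match.arg(mode)
  stopifnot(magnitude >= 0)
  m <- if (is.logical(mask)) mask else array(mask != 0, dim(mask))
  if (magnitude == 0) return(m)
  set.seed(seed)
  switch(mode,
    dilate = {
      for (i in seq_len(round(magnitude))) m <- .dilate1(m)
      m
    },
    erode = {
      for (i in seq_len(round(magnitude))) m <- .erode1(m)
      m
    },
    boundary_noise = {
      p <- min(1, magnitude)
      inner <- m & !.erode1(m)
      outer <- .dilate1(m) & !m
      flip <- array(FALSE, dim(m))
      idx <- which(inner | outer)
      flip[idx] <- stats::runif(length(idx)) < p
      xor(m, flip)
    },
    shift = {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      off <- round(magnitude * u / spacing)
      .shiftMask(m, off)
    })
}

# ---------------------------------------------------------------------------
# PairedSample
# ---------------------------------------------------------------------------

#' PairedSample: one phantom's full training/evaluation unit
#'
#' Bundles the clean CT, its CBCT degradation, the deformably registered CT
#' with its mismatch mask, the structure set, and the reference dose — all on
#' one grid.
#'
#' @slot ct,cbct,registeredCT [ImageVolume-class] members.
#' @slot mismatchMask logical array marking the region replaced in the
#'   registered CT (always a subset of the body mask).
#' @slot structures [StructureSet-class].
#' @slot refDose [DoseGrid-class].
#' @export
setClass("PairedSample",
  representation(ct = "ImageVolume", cbct = "ImageVolume",
                 registeredCT = "ImageVolume", mismatchMask = "array",
                 structures = "StructureSet", refDose = "DoseGrid"))

setValidity("PairedSample", function(object) {
  msg <- character()
  d <- dim(object@ct@voxels)
  for (nm in c("cbct", "registeredCT")) {
    if (!identical(dim(slot(object, nm)@voxels), d))
      msg <- c(msg, sprintf("'%s' grid differs from 'ct'", nm))
  }
  if (!identical(dim(object@mismatchMask), d))
    msg <- c(msg, "'mismatchMask' grid differs from 'ct'")
  if (!identical(object@structures@dim, d))
    msg <- c(msg, "'structures' grid differs from 'ct'")
  if (!identical(dim(object@refDose@dose), d))
    msg <- c(msg, "'refDose' grid differs from 'ct'")
  if ("body" %in% names(object@structures@masks) &&
      any(object@mismatchMask & !object@structures@masks[["body"]]))
    msg <- c(msg, "'mismatchMask' must be contained in the body mask")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairedSample", function(object) {
  d <- dim(object@ct@voxels)
  cat(sprintf("PairedSample %dx%dx%d (%d structures, mismatch %d voxels)\n",
              d[1], d[2], d[3], length(object@structures@masks),
              sum(object@mismatchMask)))
})

#' Generate one complete paired phantom sample
#'
#' Runs the full generation chain: [makePhantomCT()], [degradeToCBCT()],
#' [makeRegisteredCT()] and [makeDose()], all driven by sub-seeds derived
#' deterministically from `seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed.
#' @param curve [REDCurve-class] for the dose model.
#' @param withDose compute the reference dose (the slowest stage); set
#'   `FALSE` when assembling training cohorts, leaving a zero dose grid.
#' @return A [PairedSample-class].
#' @export
makePairedSample <- function(spec, seed, curve = defaultREDCurve(),
                             withDose = TRUE) {
  ph <- makePhantomCT(spec, seed)
  cbct <- degradeToCBCT(ph$ct, spec, seed + 1000L)
  reg <- makeRegisteredCT(ph$ct, ph$structures, spec, seed + 2000L)
  dose <- if (withDose) makeDose(ph$ct, spec, curve)
          else doseGrid(array(0, dim(ph$ct@voxels)), spec@spacing, spec@origin)
  new("PairedSample", ct = ph$ct, cbct = cbct, registeredCT = reg$registeredCT,
      mismatchMask = reg$mismatchMask, structures = ph$structures,
      refDose = dose)
}

#' Generate a training cohort with an occasional registration mismatch
#'
#' Builds `n` paired samples with consecutive seeds derived from `seed`. A
#' seeded fraction of samples carries the structural mismatch (structure
#' present in the CBCT but absent from the registered CT); in the remainder
#' the registered CT retains the structure, as in clinical cohorts where
#' day-to-day gas accumulation only sometimes disagrees between CBCT and the
#' deformably registered planning CT. Matched samples are what let the
#' translation model learn to reproduce such structures at all; the
#' mismatched minority is where the thresholded SSIM weighting must shield
#' the model from contradictory supervision.
#'
#' @param n number of samples.
#' @param seed integer seed; sample `i` uses `seed + 10000 * i`.
#' @param spec a [PhantomSpec-class] (its `mismatchStructure` names the
#'   structure affected in mismatch samples).
#' @param mismatchFraction fraction of samples with the mismatch
#'   (default 0.3).
#' @param withDose compute reference doses (default `FALSE`; training does
#'   not need them).
#' @return List of [PairedSample-class] objects.
#' @export
makeTrainingCohort <- function(n, seed, spec = phantomSpec(),
                               mismatchFraction = 0.3, withDose = FALSE) {
  set.seed(seed)
  nMis <- round(mismatchFraction * n)
  misIdx <- if (nMis > 0) sample.int(n, nMis) else integer()
  noMis <- spec
  noMis@mismatchStructure <- NA_character_
  lapply(seq_len(n), function(i)
    makePairedSample(if (i %in% misIdx) spec else noMis,
                     seed = seed + 10000L * i, withDose = withDose))
}
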