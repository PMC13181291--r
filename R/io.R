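# NIfTI-1 I/O and field-of-view cropping. Volumes are written with the
# spacing/origin encoded in an axis-aligned affine; HU as 16-bit signed
# integers, dose as 32-bit float, masks as 16-bit 0/1. Oblique (non
# axis-aligned) orientations are not supported.

.niftiGeom <- function(img) {
  x <- unclass(RNifti::xform(img))
  rot <- x[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0)) stop("NIfTI affine has degenerate spacing")
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6 * max(spacing)) || any(diag(rot) < 0))
    stop("oblique or flipped NIfTI orientation is unsupported")
  list(spacing = as.numeric(diag(rot)), origin = as.numeric(x[1:3, 4]))
}

.writeNifti <- function(arr, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write image volumes, dose grids and masks as NIfTI-1
#'
#' `writeVolume()` stores HU rounded to 16-bit signed integers (a write/read
#' round trip of integer-valued HU is bitwise exact); `writeDose()` stores
#' 32-bit float; `writeMask()` stores 0/1. Spacing and origin ride in the
#' qform affine and survive the round trip to within 1e-6 mm.
#'
#' @param vol an [ImageVolume-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return Readers return the corresponding object; writers the path,
#'   invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  .writeNifti(round(vol@voxels), vol@spacing, vol@origin, path, "int16")
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  g <- .niftiGeom(img)
  imageVolume(array(as.numeric(img), dim(img)), g$spacing, g$origin)
}

#' @rdname writeVolume
#' @param dose a [DoseGrid-class].
#' @export
writeDose <- function(dose, path) {
  stopifnot(is(dose, "DoseGrid"))
  .writeNifti(dose@dose, dose@spacing, dose@origin, path, "float")
}

#' @rdname writeVolume
#' @export
readDose <- function(path) {
  img <- RNifti::readNifti(path)
  g <- .niftiGeom(img)
  d <- array(as.numeric(img), dim(img))
  d[d < 0 & d > -1e-6] <- 0  # float32 round-off guard
  doseGrid(d, g$spacing, g$origin)
}

#' @rdname writeVolume
#' @param mask binary 3D array.
#' @param spacing,origin grid geometry for the mask writer.
#' @export
writeMask <- function(mask, spacing, origin, path) {
  .writeNifti(array(as.integer(.asMask(mask)), dim(mask)), spacing, origin,
              path, "int16")
}

#' @rdname writeVolume
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  g <- .niftiGeom(img)
  list(mask = array(as.numeric(img) != 0, dim(img)), spacing = g$spacing,
       origin = g$origin)
}

# ---------------------------------------------------------------------------
# FOV cropping
# ---------------------------------------------------------------------------

#' FOVSpec: an axis-aligned field-of-view box
#'
#' Defined either as a centre + extents box in mm, or directly as inclusive
#' voxel index ranges. An axis-aligned box approximates the cylindrical CBCT
#' field of view.
#'
#' @slot centerMM,extentMM box centre and edge lengths in mm (mm mode).
#' @slot indexLo,indexHi inclusive voxel index ranges (index mode).
#' @slot useIndex which mode is active.
#' @export
setClass("FOVSpec",
  representation(centerMM = "numeric", extentMM = "numeric",
                 indexLo = "integer", indexHi = "integer",
                 useIndex = "logical"))

setValidity("FOVSpec", function(object) {
  if (object@useIndex) {
    if (any(object@indexHi < object@indexLo))
      return("index ranges must be nondecreasing")
  } else if (any(object@extentMM <= 0))
    return("box extents must be positive")
  TRUE
})

#' @rdname FOVSpec-class
#' @param centerMM,extentMM box centre and extents in mm.
#' @export
fovSpec <- function(centerMM, extentMM) {
  new("FOVSpec", centerMM = as.numeric(centerMM),
      extentMM = as.numeric(extentMM), indexLo = integer(3),
      indexHi = integer(3), useIndex = FALSE)
}

#' @rdname FOVSpec-class
#' @param indexLo,indexHi inclusive 1-based voxel index ranges.
#' @export
fovSpecIndex <- function(indexLo, indexHi) {
  new("FOVSpec", centerMM = numeric(3), extentMM = numeric(3),
      indexLo = as.integer(indexLo), indexHi = as.integer(indexHi),
      useIndex = TRUE)
}

.fovIndexRange <- function(fov, dims, spacing, origin) {
  if (fov@useIndex) {
    lo <- pmax(fov@indexLo, 1L); hi <- pmin(fov@indexHi, dims)
  } else {
    lo <- hi <- integer(3)
    for (a in 1:3) {
      x <- origin[a] + (seq_len(dims[a]) - 1) * spacing[a]
      inside <- which(x >= fov@centerMM[a] - fov@extentMM[a] / 2 - 1e-9 &
                      x <= fov@centerMM[a] + fov@extentMM[a] / 2 + 1e-9)
      if (!length(inside)) return(NULL)
      lo[a] <- min(inside); hi[a] <- max(inside)
    }
  }
  if (any(hi < lo)) return(NULL)
  list(lo = lo, hi = hi)
}

#' Crop an object to a field of view
#'
#' Voxels outside the box are removed and the origin updated. Structure sets
#' are trimmed mask-by-mask; a structure left empty by the crop is an error
#' (a silently emptied contour would hide an upstream failure).
#'
#' @param x an [ImageVolume-class], [DoseGrid-class] or
#'   [StructureSet-class].
#' @param fov a [FOVSpec-class].
#' @return The cropped object of the same class.
#' @export
setGeneric("cropToFOV", function(x, fov) standardGeneric("cropToFOV"))

.cropRange <- function(x, fov) {
  r <- .fovIndexRange(fov, gridDim(x), spacing(x), origin(x))
  if (is.null(r)) stop("FOV does not intersect the grid")
  r
}

#' @rdname cropToFOV
#' @export
setMethod("cropToFOV", "ImageVolume", function(x, fov) {
  r <- .cropRange(x, fov)
  imageVolume(x@voxels[r$lo[1]:r$hi[1], r$lo[2]:r$hi[2], r$lo[3]:r$hi[3],
                       drop = FALSE],
              x@spacing, x@origin + (r$lo - 1) * x@spacing)
})

#' @rdname cropToFOV
#' @export
setMethod("cropToFOV", "DoseGrid", function(x, fov) {
  r <- .cropRange(x, fov)
  doseGrid(x@dose[r$lo[1]:r$hi[1], r$lo[2]:r$hi[2], r$lo[3]:r$hi[3],
                  drop = FALSE],
           x@spacing, x@origin + (r$lo - 1) * x@spacing)
})

#' @rdname cropToFOV
#' @export
setMethod("cropToFOV", "StructureSet", function(x, fov) {
  r <- .cropRange(x, fov)
  cropped <- lapply(names(x@masks), function(nm) {
    m <- x@masks[[nm]][r$lo[1]:r$hi[1], r$lo[2]:r$hi[2], r$lo[3]:r$hi[3],
                       drop = FALSE]
    if (!any(m)) stop("structure '", nm, "' lies entirely outside the FOV")
    m
  })
  names(cropped) <- names(x@masks)
  structureSet(cropped, x@spacing, x@origin + (r$lo - 1) * x@spacing)
})
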