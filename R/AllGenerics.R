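# Accessor generics for the grid-based containers. All three containers share
# spacing/origin geometry; voxel [i,j,k] centre = origin + (c(i,j,k)-1)*spacing.

#' @rdname ImageVolume-class
#' @param object,x an object.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname ImageVolume-class
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname ImageVolume-class
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' @rdname ImageVolume-class
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))

#' @rdname StructureSet-class
#' @param object an object.
#' @export
setGeneric("masks", function(object) standardGeneric("masks"))

#' @rdname DoseGrid-class
#' @param object an object.
#' @export
setGeneric("doseValues", function(object) standardGeneric("doseValues"))

#' @rdname ImageVolume-class
#' @export
setMethod("voxels", "ImageVolume", function(object) object@voxels)

#' @rdname ImageVolume-class
#' @export
setMethod("spacing", "ImageVolume", function(object) object@spacing)
#' @rdname StructureSet-class
#' @export
setMethod("spacing", "StructureSet", function(object) object@spacing)
#' @rdname DoseGrid-class
#' @export
setMethod("spacing", "DoseGrid", function(object) object@spacing)

#' @rdname ImageVolume-class
#' @export
setMethod("origin", "ImageVolume", function(object) object@origin)
#' @rdname StructureSet-class
#' @export
setMethod("origin", "StructureSet", function(object) object@origin)
#' @rdname DoseGrid-class
#' @export
setMethod("origin", "DoseGrid", function(object) object@origin)

#' @rdname ImageVolume-class
#' @export
setMethod("gridDim", "ImageVolume", function(object) dim(object@voxels))
#' @rdname StructureSet-class
#' @export
setMethod("gridDim", "StructureSet", function(object) object@dim)
#' @rdname DoseGrid-class
#' @export
setMethod("gridDim", "DoseGrid", function(object) dim(object@dose))

#' @rdname StructureSet-class
#' @export
setMethod("masks", "StructureSet", function(object) object@masks)

#' @rdname DoseGrid-class
#' @export
setMethod("doseValues", "DoseGrid", function(object) object@dose)

#' @rdname StructureSet-class
#' @export
setMethod("names", "StructureSet", function(x) names(x@masks))

#' @rdname StructureSet-class
#' @param i structure name or index.
#' @export
setMethod("[[", "StructureSet", function(x, i) {
  m <- x@masks[[i]]
  if (is.null(m)) stop("no structure named '", i, "'")
  m
})
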