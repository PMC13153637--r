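#' @rdname ImagingGeometry-class
#' @param x an object.
#' @export
setGeneric("imageSize", function(x) standardGeneric("imageSize"))

#' @rdname ImagingGeometry-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname Image2D-class
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname CoupledShift-class
#' @export
setGeneric("shiftUnit", function(x) standardGeneric("shiftUnit"))

#' Convert a coupled shift between pixels and mm
#'
#' @param x a \linkS4class{CoupledShift}.
#' @param unit target unit, \code{"pixels"} or \code{"mm"}.
#' @param geometry an \linkS4class{ImagingGeometry} supplying the pixel
#'   spacing used for the conversion.
#' @return a \linkS4class{CoupledShift} in the requested unit.
#' @export
setGeneric("convertShift",
           function(x, unit, geometry) standardGeneric("convertShift"))

#' @rdname MotionModel-class
#' @param x an object.
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))

#' @rdname MotionModel-class
#' @export
setGeneric("cutoffRatio", function(x) standardGeneric("cutoffRatio"))

#' @rdname MotionModel-class
#' @export
setGeneric("retainedValues", function(x) standardGeneric("retainedValues"))

#' @rdname DoseGrid-class
#' @param x an object.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname DoseGrid-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname DoseGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

setMethod("imageSize", "ImagingGeometry", function(x) x@imageSize)
setMethod("pixelSpacing", "ImagingGeometry", function(x) x@pixelSpacing)
setMethod("pixelSpacing", "Image2D", function(x) x@pixelSpacing)
setMethod("pixelData", "Image2D", function(x) x@pixels)
setMethod("shiftUnit", "CoupledShift", function(x) x@unit)
setMethod("coefMatrix", "MotionModel", function(x) x@coefficients)
setMethod("cutoffRatio", "MotionModel", function(x) x@cutoffRatio)
setMethod("retainedValues", "MotionModel", function(x) x@retained)
setMethod("voxelData", "DoseGrid", function(x) x@voxels)
setMethod("voxelSpacing", "DoseGrid", function(x) x@spacing)
setMethod("gridOrigin", "DoseGrid", function(x) x@origin)
setMethod("voxelData", "StructureMask", function(x) x@voxels)
setMethod("voxelSpacing", "StructureMask", function(x) x@spacing)
setMethod("gridOrigin", "StructureMask", function(x) x@origin)

setMethod("convertShift", "CoupledShift", function(x, unit, geometry) {
  stopifnot(unit %in% c("pixels", "mm"))
  if (x@unit == unit) return(x)
  sp <- pixelSpacing(geometry)
  f <- if (unit == "mm") sp else 1 / sp
  CoupledShift(x@iA * f, x@iB * f, x@jAB * f, unit = unit)
})

setMethod("show", "ImagingGeometry", function(object) {
  cat("ImagingGeometry:", object@imageSize, "x", object@imageSize,
      "px,", object@pixelSpacing, "mm/px, views at +/-45 deg\n")
})

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat("Image2D:", d[1], "x", d[2], "px,", object@pixelSpacing, "mm/px,",
      "intensity range [", signif(min(object@pixels), 4), ",",
      signif(max(object@pixels), 4), "]\n")
})

setMethod("show", "CoupledShift", function(object) {
  cat(sprintf("CoupledShift: iA=%.3f iB=%.3f jAB=%.3f [%s]\n",
              object@iA, object@iB, object@jAB, object@unit))
})

setMethod("show", "RegistrationVector", function(object) {
  cat("RegistrationVector (104 components, mm); patient",
      object@patient, "fraction", object@fraction, "image", object@image, "\n")
})

setMethod("show", "MotionModel", function(object) {
  cat(sprintf("MotionModel (%s): 105 x 3 coefficients, R = %g, %d/%d singular values retained, fitted on %d observations\n",
              object@kind, object@cutoffRatio, object@retained,
              min(object@nObs, 105L), object@nObs))
})

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@voxels)
  cat("DoseGrid:", paste(d, collapse = " x "), "voxels at",
      paste(object@spacing, collapse = " x "), "mm; max",
      signif(max(object@voxels), 4), "\n")
})

setMethod("show", "StructureMask", function(object) {
  cat("StructureMask '", object@label, "': ", sum(object@voxels),
      " voxels (", signif(sum(object@voxels) * prod(object@spacing) / 1000, 4),
      " cm^3)\n", sep = "")
})
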