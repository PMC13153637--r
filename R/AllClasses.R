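#' @import methods
NULL

#' Imaging geometry of the orthogonal kV pair
#'
#' Describes the fixed stereo geometry of the two kV imagers: square images of
#' \code{imageSize} pixels with \code{pixelSpacing} mm per pixel at the target
#' plane, projection axes at +/-45 degrees from vertical in the axial plane, and
#' the image vertical axis along the patient superior--inferior direction.
#' Parallel-ray projection is assumed; the back-projection constant is
#' \eqn{R = \sqrt{2}/2}.
#'
#' @slot imageSize integer, pixels per side (default 320).
#' @slot pixelSpacing numeric, mm per pixel at the target plane (default 1).
#'
#' @examples
#' g <- ImagingGeometry(imageSize = 128, pixelSpacing = 2)
#' imageSize(g)
#' @export
setClass("ImagingGeometry",
  representation(imageSize = "integer", pixelSpacing = "numeric"),
  prototype(imageSize = 320L, pixelSpacing = 1.0))

setValidity("ImagingGeometry", function(object) {
  msg <- character()
  if (length(object@imageSize) != 1L || is.na(object@imageSize) ||
      object@imageSize < 64L)
    msg <- c(msg, "imageSize must be a single integer >= 64")
  if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname ImagingGeometry-class
#' @param imageSize pixels per side.
#' @param pixelSpacing mm per pixel.
#' @export
ImagingGeometry <- function(imageSize = 320L, pixelSpacing = 1.0) {
  new("ImagingGeometry", imageSize = as.integer(imageSize),
      pixelSpacing = as.numeric(pixelSpacing))
}

#' A single 2D attenuation-style projection image
#'
#' Holds one square projection image (DRR or treatment image). Pixels are
#' stored as a numeric matrix indexed \code{[row, col]}; rows run
#' superior-to-inferior down the detector, columns run along the in-plane
#' lateral axis of the view. Intensities are line integrals of density times
#' the attenuation coefficient, so dense anatomy is bright.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot pixelSpacing numeric, mm per pixel at the target plane.
#'
#' @export
setClass("Image2D",
  representation(pixels = "matrix", pixelSpacing = "numeric"))

setValidity("Image2D", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  if (any(!is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
  if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname Image2D-class
#' @param pixels numeric matrix.
#' @param pixelSpacing mm per pixel.
#' @export
Image2D <- function(pixels, pixelSpacing = 1.0) {
  new("Image2D", pixels = pixels, pixelSpacing = as.numeric(pixelSpacing))
}

#' Coupled image-plane shift of the orthogonal view pair
#'
#' The three degrees of freedom linking the two views: independent lateral
#' shifts \code{iA} and \code{iB} of images A and B, and a shared
#' superior--inferior shift \code{jAB} common to both. The unit flag records
#' whether the components are in pixels or mm; conversion between the two uses
#' the geometry's pixel spacing exactly.
#'
#' @slot iA numeric, lateral shift of image A.
#' @slot iB numeric, lateral shift of image B.
#' @slot jAB numeric, shared superior--inferior shift.
#' @slot unit character, one of \code{"pixels"} or \code{"mm"}.
#'
#' @export
setClass("CoupledShift",
  representation(iA = "numeric", iB = "numeric", jAB = "numeric",
                 unit = "character"),
  prototype(unit = "mm"))

setValidity("CoupledShift", function(object) {
  msg <- character()
  if (!all(vapply(list(object@iA, object@iB, object@jAB),
                  function(v) length(v) == 1L && is.finite(v), logical(1))))
    msg <- c(msg, "iA, iB, jAB must be single finite numbers")
  if (length(object@unit) != 1L || !object@unit %in% c("pixels", "mm"))
    msg <- c(msg, "unit must be 'pixels' or 'mm'")
  if (length(msg)) msg else TRUE
})

#' @rdname CoupledShift-class
#' @param iA,iB,jAB shift components.
#' @param unit \code{"pixels"} or \code{"mm"}.
#' @export
CoupledShift <- function(iA, iB, jAB, unit = "mm") {
  new("CoupledShift", iA = as.numeric(iA), iB = as.numeric(iB),
      jAB = as.numeric(jAB), unit = unit)
}

#' The 104-component image-space motion state of one image pair
#'
#' Stacks the (I, J) shifts of the 25 grid subregions plus the PTV region of
#' image A, followed by the same 26 pairs for image B, all in mm:
#' component order is
#' \code{[A grid(1,1) I, A grid(1,1) J, ..., A grid(5,5) J, A ptv I, A ptv J,
#' B grid(1,1) I, ..., B ptv J]}, giving exactly 104 numbers. Grid regions are
#' enumerated row-major (row index fastest over columns, i.e. (row 1, col 1),
#' (row 1, col 2), ...). The motion model depends on this ordering.
#'
#' @slot values numeric vector of length 104 (mm).
#' @slot patient,fraction,image integer indices of provenance.
#'
#' @export
setClass("RegistrationVector",
  representation(values = "numeric", patient = "integer",
                 fraction = "integer", image = "integer"),
  prototype(patient = NA_integer_, fraction = NA_integer_, image = NA_integer_))

setValidity("RegistrationVector", function(object) {
  if (length(object@values) != 104L)
    return("values must have length exactly 104")
  if (any(!is.finite(object@values)))
    return("values must be finite")
  TRUE
})

#' @rdname RegistrationVector-class
#' @param values numeric length-104 vector (mm).
#' @param patient,fraction,image provenance indices.
#' @export
RegistrationVector <- function(values, patient = NA_integer_,
                               fraction = NA_integer_, image = NA_integer_) {
  new("RegistrationVector", values = as.numeric(values),
      patient = as.integer(patient), fraction = as.integer(fraction),
      image = as.integer(image))
}

#' Linear motion model from image space to patient space
#'
#' A 105 x 3 coefficient matrix mapping the 104-component registration vector
#' (plus an intercept) to the 3D target position (x, y, z) in mm, fitted by
#' truncated singular value decomposition. \code{cutoffRatio} is the singular
#' value cutoff ratio R (singular values below \eqn{w_{max}/R} are dropped);
#' \code{retained} is the number of singular values kept; \code{kind} labels
#' the model as inter- or intra-fraction.
#'
#' @slot coefficients numeric 105 x 3 matrix.
#' @slot kind character, \code{"inter"} or \code{"intra"}.
#' @slot cutoffRatio numeric, singular value cutoff ratio R.
#' @slot retained integer, retained singular value count.
#' @slot nObs integer, number of training observations.
#'
#' @export
setClass("MotionModel",
  representation(coefficients = "matrix", kind = "character",
                 cutoffRatio = "numeric", retained = "integer",
                 nObs = "integer"))

setValidity("MotionModel", function(object) {
  msg <- character()
  if (!identical(dim(object@coefficients), c(105L, 3L)))
    msg <- c(msg, "coefficients must be a 105 x 3 matrix")
  if (any(!is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be finite")
  if (!object@kind %in% c("inter", "intra"))
    msg <- c(msg, "kind must be 'inter' or 'intra'")
  if (object@retained > min(object@nObs, 105L))
    msg <- c(msg, "retained count cannot exceed min(nObs, 105)")
  if (length(msg)) msg else TRUE
})

#' A 3D dose or density grid
#'
#' A regular 3D grid of values with voxel spacing (mm) and origin (mm, the
#' physical coordinate of voxel [1,1,1] centre). Axes are patient x
#' (left-right), y (antero-posterior), z (supero-inferior). Used both for dose
#' (Gy) and for density volumes.
#'
#' @slot voxels numeric 3D array.
#' @slot spacing numeric length-3 vector, mm.
#' @slot origin numeric length-3 vector, mm.
#'
#' @export
setClass("DoseGrid",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "voxels must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (length(msg)) msg else TRUE
})

#' @rdname DoseGrid-class
#' @param voxels 3D numeric array.
#' @param spacing voxel spacing, mm (length 3 or scalar).
#' @param origin physical position of the first voxel centre, mm.
#' @export
DoseGrid <- function(voxels, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DoseGrid", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' A binary structure mask aligned to a dose grid
#'
#' @slot voxels logical 3D array, same shape as its companion DoseGrid.
#' @slot spacing numeric length-3 vector, mm.
#' @slot origin numeric length-3 vector, mm.
#' @slot label character structure name (CTV, PTV, stomach, duodenum, bowel).
#'
#' @export
setClass("StructureMask",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 label = "character"))

setValidity("StructureMask", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L || !is.logical(object@voxels))
    msg <- c(msg, "voxels must be a logical 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' @rdname StructureMask-class
#' @param voxels logical 3D array.
#' @param spacing voxel spacing, mm.
#' @param origin grid origin, mm.
#' @param label structure name.
#' @export
StructureMask <- function(voxels, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                          label = "structure") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("StructureMask", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), label = label)
}
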