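## Stereo geometry of the orthogonal kV pair.
##
## The two imagers view the patient at +/-45 degrees from vertical in the
## axial plane, so a lateral image shift mixes patient x (left-right) and
## y (antero-posterior), while the image vertical axis carries z
## (supero-inferior) in both views simultaneously.  Sign conventions: x
## positive toward patient left, y positive anterior, z positive superior;
## image I positive toward increasing column index, J positive toward
## increasing row index (inferior-down display), which makes z = -J literal.

#' Back-projection constant of the +/-45 degree stereo geometry
#' @keywords internal
.R_CONST <- sqrt(2) / 2

#' Back-project a coupled image shift to a 3D target displacement
#'
#' Converts the three image-plane degrees of freedom (lateral shifts
#' \eqn{I_A}, \eqn{I_B} and shared vertical shift \eqn{J_{AB}}, in mm) into a
#' patient-space displacement via
#' \deqn{x = R(I_A + I_B), \quad y = R(I_B - I_A), \quad z = -J_{AB},}
#' with \eqn{R = \sqrt{2}/2}.
#'
#' @param shift a \linkS4class{CoupledShift} in mm, or a numeric length-3
#'   vector \code{c(iA, iB, jAB)} in mm.
#' @return numeric length-3 vector \code{c(x, y, z)} in mm.
#' @seealso [projectOffset()] for the exact inverse.
#' @examples
#' backprojectShift(CoupledShift(1, 1, 0))   # c(sqrt(2), 0, 0)
#' @export
backprojectShift <- function(shift) {
  v <- .shiftComponents(shift, "backprojectShift")
  R <- .R_CONST
  c(x = R * (v[1] + v[2]), y = R * (v[2] - v[1]), z = -v[3])
}

#' Project a 3D target displacement to the coupled image shift
#'
#' The algebraic inverse of [backprojectShift()]:
#' \eqn{I_A = R(x - y)}, \eqn{I_B = R(x + y)}, \eqn{J_{AB} = -z} with
#' \eqn{R = \sqrt{2}/2}. \code{backprojectShift(projectOffset(v))} is the
#' identity to machine precision.
#'
#' @param offset numeric length-3 vector \code{c(x, y, z)} in mm.
#' @return a \linkS4class{CoupledShift} in mm.
#' @examples
#' projectOffset(c(sqrt(2), 0, 0))   # iA = iB = 1, jAB = 0
#' @export
projectOffset <- function(offset) {
  if (!is.numeric(offset) || length(offset) != 3L || any(!is.finite(offset)))
    stop("offset must be a finite numeric vector of length 3")
  R <- .R_CONST
  CoupledShift(iA = R * (offset[1] - offset[2]),
               iB = R * (offset[1] + offset[2]),
               jAB = -offset[3], unit = "mm")
}

.shiftComponents <- function(shift, caller) {
  if (is(shift, "CoupledShift")) {
    if (shift@unit != "mm")
      stop(caller, " expects a shift in mm; use convertShift() first")
    v <- c(shift@iA, shift@iB, shift@jAB)
  } else if (is.numeric(shift) && length(shift) == 3L) {
    v <- as.numeric(shift)
  } else {
    stop(caller, " expects a CoupledShift or numeric length-3 vector")
  }
  if (any(!is.finite(v))) stop(caller, ": non-finite shift components")
  v
}
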