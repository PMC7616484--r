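#' Spatial and temporal calibration
#'
#' Physical size of one pixel / slice / frame, carried by images and object
#' sets so measurements can be reported in both pixel and calibrated units.
#'
#' @slot dx,dy physical length per pixel in x and y (e.g. micrometres/px).
#' @slot dz physical length per z-slice.
#' @slot spatialUnit name of the spatial unit (default "micron").
#' @slot frameInterval time elapsed between consecutive frames.
#' @slot timeUnit name of the time unit (default "s").
#' @export
setClass("SpatialCalibration",
  representation(
    dx = "numeric", dy = "numeric", dz = "numeric",
    spatialUnit = "character",
    frameInterval = "numeric", timeUnit = "character"
  ),
  prototype(
    dx = 1, dy = 1, dz = 1, spatialUnit = "pixel",
    frameInterval = 1, timeUnit = "frame"
  ),
  validity = function(object) {
    v <- c(dx = object@dx, dy = object@dy, dz = object@dz,
           frameInterval = object@frameInterval)
    if (any(!is.finite(v)) || any(v <= 0))
      return("dx, dy, dz and frameInterval must be finite and > 0")
    TRUE
  }
)

#' Create a spatial calibration
#'
#' @param dx,dy,dz physical length per pixel (x, y) and per slice (z); must
#'   be positive.
#' @param spatialUnit spatial unit name.
#' @param frameInterval time per frame; must be positive.
#' @param timeUnit time unit name.
#' @return A \code{SpatialCalibration} object.
#' @examples
#' SpatialCalibration(dx = 0.5, dy = 0.5, dz = 2, spatialUnit = "micron")
#' @export
SpatialCalibration <- function(dx = 1, dy = 1, dz = 1, spatialUnit = "pixel",
                               frameInterval = 1, timeUnit = "frame") {
  new("SpatialCalibration", dx = dx, dy = dy, dz = dz,
      spatialUnit = spatialUnit, frameInterval = frameInterval,
      timeUnit = timeUnit)
}

#' @describeIn SpatialCalibration physical pixel sizes as c(dx, dy, dz).
#' @param object,cal a \code{SpatialCalibration}.
#' @export
pixelSize <- function(cal) c(x = cal@dx, y = cal@dy, z = cal@dz)

#' @describeIn SpatialCalibration time per frame.
#' @export
frameInterval <- function(cal) cal@frameInterval

setMethod("show", "SpatialCalibration", function(object) {
  cat(sprintf("SpatialCalibration: %g x %g x %g %s/px, %g %s/frame\n",
              object@dx, object@dy, object@dz, object@spatialUnit,
              object@frameInterval, object@timeUnit))
})

#' Test two calibrations for agreement
#'
#' Images and object sets that interact must share a calibration; a mismatch
#' is treated as a hard error by the modules to prevent silent unit
#' corruption.
#'
#' @param a,b \code{SpatialCalibration} objects.
#' @param tol relative tolerance.
#' @return Logical scalar.
#' @export
sameCalibration <- function(a, b, tol = 1e-9) {
  isTRUE(all.equal(c(a@dx, a@dy, a@dz, a@frameInterval),
                   c(b@dx, b@dy, b@dz, b@frameInterval), tolerance = tol)) &&
    a@spatialUnit == b@spatialUnit && a@timeUnit == b@timeUnit
}
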