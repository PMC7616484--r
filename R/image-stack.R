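#' Calibrated 5D image stacks
#'
#' An \code{ImageStack} holds a named, spatially calibrated intensity grid
#' with axes (x, y, c, z, t); absent dimensions are kept as singleton axes
#' so every image is uniformly 5D. Images are reference objects: modules
#' may update pixel data in place (the workspace keeps the same named
#' entity, and image-level measurements survive the update).
#'
#' @field name user-defined identifier, unique within a workspace.
#' @field data numeric 5D array, dim = c(nx, ny, nc, nz, nt).
#' @field calibration a \code{\link{SpatialCalibration}}.
#' @field measurements named list of image-level measurement values.
#' @export ImageStack
#' @exportClass ImageStack
ImageStack <- setRefClass("ImageStack",
  fields = list(
    name = "character",
    data = "array",
    calibration = "ANY",
    measurements = "list"
  ),
  methods = list(
    initialize = function(...) {
      initFields(name = "", data = array(0, c(1, 1, 1, 1, 1)),
                 calibration = SpatialCalibration(), measurements = list())
      callSuper(...)
      invisible(.self)
    },
    setData = function(newData) {
      "Replace pixel data in place; measurements and identity are kept."
      data <<- .as5D(newData)
      invisible(.self)
    },
    dims = function() setNames(dim(data), c("x", "y", "c", "z", "t")),
    setMeasurement = function(nm, value) {
      measurements[[nm]] <<- as.numeric(value)
      invisible(.self)
    },
    getMeasurement = function(nm) {
      if (is.null(measurements[[nm]])) NA_real_ else measurements[[nm]]
    },
    show = function() {
      d <- dims()
      cat(sprintf("<ImageStack '%s' %dx%d c=%d z=%d t=%d, range [%g, %g]>\n",
                  name, d[1], d[2], d[3], d[4], d[5],
                  min(data), max(data)))
    }
  )
)

# promote 2D (x,y), 3D (x,y,z) or 4D (x,y,z,t) grids to the 5D layout
.as5D <- function(a) {
  if (is.matrix(a)) dim(a) <- c(dim(a), 1L, 1L, 1L)
  nd <- length(dim(a))
  if (nd == 3) dim(a) <- c(dim(a)[1:2], 1L, dim(a)[3], 1L)
  else if (nd == 4) dim(a) <- c(dim(a)[1:2], 1L, dim(a)[3:4])
  else if (nd != 5) stop("image data must have 2 to 5 dimensions")
  if (any(dim(a) < 1)) stop("all five axis lengths must be >= 1")
  storage.mode(a) <- "double"
  a
}

#' Create an image stack
#'
#' @param name user-defined image name.
#' @param data matrix (x, y), or array (x, y, z), (x, y, z, t) or the full
#'   (x, y, c, z, t) layout; singleton axes are inserted for the rest.
#' @param calibration a \code{\link{SpatialCalibration}}.
#' @return An \code{ImageStack} reference object.
#' @examples
#' img <- newImageStack("Raw", matrix(runif(64), 8, 8))
#' img$dims()
#' @export
newImageStack <- function(name, data, calibration = SpatialCalibration()) {
  img <- ImageStack$new()
  img$name <- name
  img$data <- .as5D(data)
  img$calibration <- calibration
  img
}

#' Test whether an image is binary
#'
#' Binary means at most two distinct values, the smaller of which is 0 (a
#' constant-zero image is binary; a constant non-zero image is not).
#'
#' @param img an \code{ImageStack} or numeric array.
#' @return Logical scalar.
#' @export
isBinaryImage <- function(img) {
  d <- if (is(img, "ImageStack")) img$data else img
  u <- unique(as.vector(d))
  length(u) <= 2 && min(u) == 0
}

#' Extract one (x, y, z) volume at a channel and timepoint
#'
#' @param img an \code{ImageStack}.
#' @param c,t 1-based channel and frame indices.
#' @return 3D numeric array (x, y, z).
#' @export
imageVolume <- function(img, c = 1L, t = 1L) {
  v <- img$data[, , c, , t, drop = FALSE]
  dim(v) <- dim(img$data)[c(1, 2, 4)]
  v
}

#' Replace one (x, y, z) volume at a channel and timepoint
#' @param img an \code{ImageStack}.
#' @param vol 3D array matching the image's (x, y, z) extents.
#' @param c,t 1-based channel and frame indices.
#' @return \code{img}, invisibly.
#' @export
setImageVolume <- function(img, vol, c = 1L, t = 1L) {
  img$data[, , c, , t] <- vol
  invisible(img)
}
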