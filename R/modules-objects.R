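#' Identify objects by connected components labelling
#'
#' Labels the foreground of a binary, single-channel image independently
#' per timepoint, with user-selected in-plane (4 or 8) and volumetric (6 or
#' 26) connectivity, and stores one object per component. Ids are
#' sequential in scan order across timepoints; each object records its
#' frame. The voxel coordinate storage method is a user choice (spot and
#' skeleton producers elsewhere always use pointlists, where that method is
#' always the most efficient).
#'
#' @param img binary single-channel \code{\link{ImageStack}}.
#' @param name class name of the new object set.
#' @param inPlane 4 or 8.
#' @param volumetric 6 or 26 (used only when the image has > 1 slice).
#' @param storeMethod "pointlist", "quadtree" or "octree".
#' @return A new \code{\link{ObjectSet}}.
#' @export
identifyObjects <- function(img, name, inPlane = 4L, volumetric = 6L,
                            storeMethod = "pointlist") {
  if (!isBinaryImage(img)) stop("identify_objects requires a binary image")
  d <- dim(img$data)
  if (d[3] != 1L) stop("identify_objects requires a single-channel image")
  if (!inPlane %in% c(4L, 8L)) stop("in-plane connectivity must be 4 or 8")
  if (!volumetric %in% c(6L, 26L)) stop("volumetric connectivity must be 6 or 26")
  set <- ObjectSet$new(className = name, calibration = img$calibration)
  for (t in seq_len(d[5])) {
    vol <- imageVolume(img, 1L, t)
    lab <- labelComponents(vol, inPlane = inPlane,
                           volumetric = if (d[4] > 1L) volumetric else 0L)
    k <- max(lab)
    if (k == 0L) next
    idx <- which(lab > 0L)
    coords <- arrayInd(idx, dim(lab))
    labs <- lab[idx]
    for (i in seq_len(k)) {
      sel <- coords[labs == i, , drop = FALSE] - 1L
      mask <- array(FALSE, dim(lab))
      mask[sel + 1L] <- TRUE
      o <- set$newObj(timepoint = t - 1L,
                      store = storeFromMask(mask, storeMethod))
    }
  }
  set
}

#' Measure object shape
#'
#' Adds per-object measurements: \code{N_VOXELS}; \code{AREA_PX} and
#' \code{AREA_CAL} (2D sets) or \code{VOLUME_PX} and \code{VOLUME_CAL} (3D
#' sets); centroids in pixels and calibrated units; and bounding-box
#' extents. Calibrated area is N * dx * dy; calibrated volume N * dx * dy *
#' dz. Members with empty stores are skipped with missing values.
#'
#' @param objects an \code{\link{ObjectSet}}.
#' @return \code{objects}, invisibly (measurements added in place).
#' @export
measureObjectShape <- function(objects) {
  cal <- objects$calibration
  for (o in objects$objects()) {
    v <- storeVoxels(o$store)
    n <- nrow(v)
    if (!n) {
      o$setMeasurement("N_VOXELS", NA_real_)
      next
    }
    o$setMeasurement("N_VOXELS", n)
    is3D <- length(unique(v[, 3])) > 1L
    if (is3D) {
      o$setMeasurement("VOLUME_PX", n)
      o$setMeasurement("VOLUME_CAL", n * cal@dx * cal@dy * cal@dz)
    } else {
      o$setMeasurement("AREA_PX", n)
      o$setMeasurement("AREA_CAL", n * cal@dx * cal@dy)
    }
    cen <- objectCentroid(o, cal)
    o$setMeasurement("CENTROID_X_PX", cen["x"])
    o$setMeasurement("CENTROID_Y_PX", cen["y"])
    o$setMeasurement("CENTROID_Z_PX", cen["z"])
    o$setMeasurement("CENTROID_X_CAL", cen["x_cal"])
    o$setMeasurement("CENTROID_Y_CAL", cen["y_cal"])
    o$setMeasurement("CENTROID_Z_CAL", cen["z_cal"])
    o$setMeasurement("BBOX_MIN_X", min(v[, 1]))
    o$setMeasurement("BBOX_MAX_X", max(v[, 1]))
    o$setMeasurement("BBOX_MIN_Y", min(v[, 2]))
    o$setMeasurement("BBOX_MAX_Y", max(v[, 2]))
    o$setMeasurement("BBOX_MIN_Z", min(v[, 3]))
    o$setMeasurement("BBOX_MAX_Z", max(v[, 3]))
  }
  invisible(objects)
}

#' Filter objects on a measurement
#'
#' Removes (or keeps) members by comparing a named measurement against a
#' threshold. \code{mode = "remove"} drops members satisfying the
#' predicate; \code{mode = "keep"} drops the complement. Removed objects
#' are unlinked everywhere (no dangling relationship references); surviving
#' ids are unchanged. Members whose measurement is missing are handled per
#' \code{missingPolicy} ("retain", the default, or "remove").
#'
#' @param objects an \code{\link{ObjectSet}}.
#' @param measurement measurement name; unknown names (present on no
#'   member) are a validation error.
#' @param predicate one of "<", "<=", ">", ">=".
#' @param threshold numeric threshold.
#' @param mode "remove" or "keep".
#' @param missingPolicy "retain" or "remove".
#' @return \code{objects}, invisibly (filtered in place).
#' @export
filterObjects <- function(objects, measurement,
                          predicate = c("<", "<=", ">", ">="),
                          threshold, mode = c("remove", "keep"),
                          missingPolicy = c("retain", "remove")) {
  predicate <- match.arg(predicate)
  mode <- match.arg(mode)
  missingPolicy <- match.arg(missingPolicy)
  members <- objects$objects()
  if (length(members)) {
    known <- any(vapply(members, function(o)
      measurement %in% names(o$measurements), TRUE))
    if (!known)
      stop(sprintf("no member carries a measurement named '%s'", measurement))
  }
  cmp <- match.fun(predicate)
  for (o in members) {
    val <- o$getMeasurement(measurement)
    if (is.na(val)) {
      if (missingPolicy == "remove") objects$removeObj(o$id)
      next
    }
    hit <- cmp(val, threshold)
    drop <- if (mode == "remove") hit else !hit
    if (drop) objects$removeObj(o$id)
  }
  invisible(objects)
}
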