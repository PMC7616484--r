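#' Load an image stack from TIFF
#'
#' Reads a (multi-page) TIFF into the 5D (x, y, c, z, t) layout, inserting
#' singleton axes for absent dimensions. Axis sizes, bit depth and
#' calibration are taken from the JSON sidecar written by
#' \code{\link{saveImage}} when present (\code{<path>.json}); otherwise
#' pages are interpreted as a z-stack, pixel sizes fall back to the TIFF
#' x/y resolution tags when present, and failing that to dx = dy = dz = 1
#' "pixel" with a logged warning.
#'
#' @param path path to a readable TIFF file.
#' @param name workspace name for the image; defaults to the file name
#'   without extension.
#' @return An \code{\link{ImageStack}}.
#' @export
loadImage <- function(path, name = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot load image: file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE,
                                   as.is = TRUE),
                    error = function(e)
                      stop(sprintf("not a readable TIFF: %s (%s)", path,
                                   conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::fromJSON(sidecar, simplifyVector = TRUE) else NULL

  toXY <- function(pg) {
    if (length(dim(pg)) == 3) {
      # multi-sample pages are always normalised to [0, 1] on read;
      # restore the integer sample range
      bps <- attr(pg, "bits.per.sample")
      if (is.null(bps)) bps <- 8L
      aperm(pg, c(2, 1, 3)) * (2^bps - 1)
    } else t(pg)
  }
  pages <- lapply(pages, toXY)
  nx <- dim(pages[[1]])[1]; ny <- dim(pages[[1]])[2]
  pageC <- if (length(dim(pages[[1]])) == 3) dim(pages[[1]])[3] else 1L

  if (!is.null(meta)) {
    d <- as.integer(meta$dim)
    arr <- array(0, d)
    idx <- 1L
    if (pageC > 1L) {
      for (t in seq_len(d[5])) for (z in seq_len(d[4])) {
        arr[, , seq_len(pageC), z, t] <- pages[[idx]]
        idx <- idx + 1L
      }
    } else {
      for (t in seq_len(d[5])) for (z in seq_len(d[4])) for (cc in seq_len(d[3])) {
        arr[, , cc, z, t] <- pages[[idx]]
        idx <- idx + 1L
      }
    }
    if (!is.null(meta$maxint) && !is.null(meta$scale) &&
        meta$scale != meta$maxint)
      arr <- arr / meta$maxint * meta$scale
    cal <- SpatialCalibration(dx = meta$calibration$dx,
                              dy = meta$calibration$dy,
                              dz = meta$calibration$dz,
                              spatialUnit = meta$calibration$spatialUnit,
                              frameInterval = meta$calibration$frameInterval,
                              timeUnit = meta$calibration$timeUnit)
    return(newImageStack(name, arr, cal))
  }

  # no sidecar: pages become a z-stack (or c for an RGB page)
  nz <- length(pages)
  arr <- array(0, c(nx, ny, pageC, nz, 1L))
  for (z in seq_len(nz)) arr[, , , z, 1] <- pages[[z]]
  att <- attributes(pages[[1]])
  cal <- SpatialCalibration()
  if (!is.null(att$x.resolution) && att$x.resolution > 0) {
    unit <- if (!is.null(att$resolution.unit)) att$resolution.unit else "unit"
    cal <- SpatialCalibration(dx = 1 / att$x.resolution,
                              dy = 1 / ifelse(is.null(att$y.resolution) ||
                                                att$y.resolution <= 0,
                                              att$x.resolution,
                                              att$y.resolution),
                              dz = 1, spatialUnit = unit)
  } else {
    warning(sprintf(
      "no calibration metadata for '%s'; using 1 pixel units", path))
  }
  newImageStack(name, arr, cal)
}

#' Save an image stack as TIFF
#'
#' Writes a multi-page TIFF (pages in channel-fastest, then z, then t
#' order; 3-channel images are written as RGB pages) plus a JSON sidecar
#' (\code{<path>.json}) holding the axis sizes, bit depth and calibration,
#' so \code{\link{loadImage}} reproduces the stack exactly. Integer data up
#' to 16 bits round-trips bit-exactly. The target folder is created when
#' missing.
#'
#' @param img an \code{\link{ImageStack}}.
#' @param path output file path (".tif").
#' @return \code{path}, invisibly.
#' @export
saveImage <- function(img, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  d <- dim(img$data)
  mx <- max(img$data)
  integral <- all(img$data == round(img$data)) && min(img$data) >= 0
  bits <- if (!integral) 16L else if (mx <= 255) 8L else 16L
  # integer data maps 1:1 onto the sample range; float data is quantised
  scale <- if (!integral) max(mx, 1) else (2^bits - 1)
  pages <- list()
  rgb <- d[3] == 3L && bits <= 8L
  for (t in seq_len(d[5])) for (z in seq_len(d[4])) {
    if (rgb) {
      pg <- aperm(img$data[, , , z, t, drop = TRUE], c(2, 1, 3))
      pages[[length(pages) + 1]] <- pg / scale
    } else {
      for (cc in seq_len(d[3])) {
        pages[[length(pages) + 1]] <- t(img$data[, , cc, z, t]) / scale
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  cal <- img$calibration
  meta <- list(dim = d, bits = bits, scale = scale, maxint = 2^bits - 1,
               rgbPages = rgb,
               calibration = list(dx = cal@dx, dy = cal@dy, dz = cal@dz,
                                  spatialUnit = cal@spatialUnit,
                                  frameInterval = cal@frameInterval,
                                  timeUnit = cal@timeUnit))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Apply an intensity threshold
#'
#' Binarises a single-channel image: foreground (value \code{fgValue},
#' default 255) is strictly above the threshold. The automatic algorithm is
#' Otsu's method on a 256-bin histogram of min-max scaled intensities
#' (maximising between-class variance), computed globally or per z-slice.
#' Thresholding a constant image with Otsu yields an all-background result
#' with a warning, not an error.
#'
#' @param img single-channel \code{\link{ImageStack}}.
#' @param algorithm "otsu" or "manual".
#' @param manualValue threshold for the manual algorithm; must lie within
#'   the image intensity range.
#' @param scope "global" or "per-slice".
#' @param outputName workspace name of the result; defaults to the input
#'   name (in-place update semantics at the workflow level).
#' @param fgValue intensity assigned to foreground pixels.
#' @return A new binary \code{\link{ImageStack}} with values {0, fgValue}.
#' @export
applyThreshold <- function(img, algorithm = c("otsu", "manual"),
                           manualValue = NULL,
                           scope = c("global", "per-slice"),
                           outputName = NULL, fgValue = 255) {
  algorithm <- match.arg(algorithm)
  scope <- match.arg(scope)
  d <- dim(img$data)
  if (d[3] != 1L) stop("apply_threshold requires a single-channel image")
  if (algorithm == "manual") {
    if (is.null(manualValue)) stop("manual thresholding requires manualValue")
    if (manualValue < min(img$data) || manualValue > max(img$data))
      stop("manual threshold lies outside the image intensity range")
  }
  out <- array(0, d)
  if (scope == "global") {
    thr <- if (algorithm == "manual") manualValue
    else otsuThreshold(as.vector(img$data))
    if (is.na(thr)) {
      warning("constant image: Otsu threshold undefined; output is all background")
    } else {
      out[img$data > thr] <- fgValue
    }
  } else {
    for (t in seq_len(d[5])) for (z in seq_len(d[4])) {
      sl <- img$data[, , 1, z, t]
      thr <- if (algorithm == "manual") manualValue else otsuThreshold(as.vector(sl))
      if (is.na(thr)) {
        warning(sprintf("constant slice z=%d t=%d: all background", z, t))
      } else {
        out[, , 1, z, t][sl > thr] <- fgValue
      }
    }
  }
  newImageStack(if (is.null(outputName)) img$name else outputName, out,
                img$calibration)
}

#' Fill holes in a binary image
#'
#' Background regions not connected to the slice border become foreground,
#' independently per z-slice, channel and timepoint (2D filling).
#'
#' @param img binary \code{\link{ImageStack}}.
#' @param outputName output name; defaults to the input name.
#' @return A binary \code{\link{ImageStack}}.
#' @export
fillHoles <- function(img, outputName = NULL) {
  if (!isBinaryImage(img)) stop("fill_holes requires a binary image")
  d <- dim(img$data)
  fgVal <- max(img$data)
  if (fgVal == 0) fgVal <- 255
  out <- array(0, d)
  for (t in seq_len(d[5])) for (z in seq_len(d[4])) for (cc in seq_len(d[3])) {
    sl <- img$data[, , cc, z, t] > 0
    filled <- EBImage::fillHull(sl + 0)
    out[, , cc, z, t] <- (filled > 0) * fgVal
  }
  newImageStack(if (is.null(outputName)) img$name else outputName, out,
                img$calibration)
}

# per-object colours: seeded shuffle of equally spaced hues
.objectColours <- function(ids, seed) {
  n <- length(ids)
  if (!n) return(matrix(numeric(0), ncol = 3))
  hues <- (seq_len(n) - 1) / n
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  hues <- sample(hues)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  cols <- t(grDevices::col2rgb(grDevices::hsv(hues, 1, 1)))
  rownames(cols) <- as.character(ids)
  cols
}

#' Overlay object outlines on an image
#'
#' Renders the image to RGB and recolours each object's boundary pixels
#' (foreground voxels with at least one non-object 4-neighbour within the
#' slice, or lying on the image edge) with a colour drawn per object id
#' from a seeded shuffle, so reruns with the same seed give identical
#' output and distinct objects get distinct colours. Non-boundary pixels
#' keep the underlying grayscale.
#'
#' @param img grayscale \code{\link{ImageStack}}.
#' @param objects an \code{\link{ObjectSet}} sharing the image's
#'   calibration and extents.
#' @param seed integer colour-shuffle seed.
#' @param outputName name of the RGB output image.
#' @return An RGB \code{\link{ImageStack}} (c = 3).
#' @export
addOutlineOverlay <- function(img, objects, seed = 42L,
                              outputName = "Overlay") {
  if (!sameCalibration(img$calibration, objects$calibration))
    stop("image and object set calibrations do not match")
  d <- dim(img$data)
  out <- array(0, c(d[1], d[2], 3L, d[4], d[5]))
  for (cc in 1:3) out[, , cc, , ] <- img$data[, , 1, , ]
  ids <- objects$ids()
  # colours use the image's dynamic range so overlays survive rescaling
  cols <- .objectColours(ids, seed) / 255 * max(img$data, 1)
  for (o in objects$objects()) {
    v <- storeVoxels(o$store)
    if (!nrow(v)) next
    if (any(v[, 1] >= d[1]) || any(v[, 2] >= d[2]) || any(v[, 3] >= d[4]))
      stop("object extends beyond the image extents")
    tt <- o$timepoint + 1L
    if (tt > d[5]) stop("object timepoint beyond the image extents")
    col <- cols[as.character(o$id), ]
    for (z in unique(v[, 3])) {
      sel <- v[v[, 3] == z, , drop = FALSE]
      m <- matrix(FALSE, d[1], d[2])
      m[cbind(sel[, 1] + 1L, sel[, 2] + 1L)] <- TRUE
      # a pixel is interior iff all four in-slice neighbours are in-object
      shifted <- function(dx, dy) {
        s <- matrix(FALSE, d[1], d[2])
        xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy
        okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
        s[okx, oky] <- m[xs[okx], ys[oky]]
        s
      }
      interior <- m & shifted(1, 0) & shifted(-1, 0) &
        shifted(0, 1) & shifted(0, -1)
      boundary <- which(m & !interior, arr.ind = TRUE)
      for (cc in 1:3) {
        out[cbind(boundary[, 1], boundary[, 2], cc, z + 1L, tt)] <- col[cc]
      }
    }
  }
  newImageStack(outputName, out, img$calibration)
}
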