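#' Seeded synthetic fixtures
#'
#' Pure, seeded generators producing images together with their ground
#' truth, so every downstream behaviour (segmentation, tracking, skeleton
#' decomposition, store costs) can be verified without external data. All
#' generators restore the caller's RNG state.
#'
#' @name fixtures
NULL

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

.diskMask <- function(width, height, cx, cy, r) {
  xs <- matrix(seq_len(width) - 1, width, height)
  ys <- matrix(rep(seq_len(height) - 1, each = width), width, height)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Synthetic blob image with ground truth
#'
#' Bright disks on a dark noisy background. Blobs are placed by rejection
#' sampling so they never overlap or touch; background noise is kept well
#' below the foreground contrast so automatic thresholding recovers the
#' truth unambiguously. Intensities: background 30 +/- noise, blobs 200.
#'
#' @param nBlobs number of disks.
#' @param width,height image extent in pixels.
#' @param radiusRange min/max disk radius (pixels); each blob's radius is
#'   drawn uniformly. Pass fixed values via c(r, r).
#' @param seed RNG seed (generators are pure functions of their
#'   parameters and seed).
#' @param noiseSd background noise standard deviation.
#' @return List: \code{image} (an \code{\link{ImageStack}}),
#'   \code{truth} (data.frame id, cx, cy, radius, area_px) and
#'   \code{labels} (integer matrix).
#' @export
makeBlobImage <- function(nBlobs = 5, width = 128, height = 128,
                          radiusRange = c(4, 12), seed = 1,
                          noiseSd = 5) {
  .withSeed(seed, {
    placed <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                         radius = numeric(0))
    tries <- 0
    while (nrow(placed) < nBlobs) {
      tries <- tries + 1
      if (tries > 5000)
        stop("could not place blobs without overlap; reduce nBlobs or radii")
      r <- runif(1, radiusRange[1], radiusRange[2])
      cx <- runif(1, r + 2, width - r - 3)
      cy <- runif(1, r + 2, height - r - 3)
      if (nrow(placed) &&
          any(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) <
                placed$radius + r + 4)) next
      placed <- rbind(placed, data.frame(id = nrow(placed) + 1L,
                                         cx = cx, cy = cy, radius = r))
    }
    labels <- matrix(0L, width, height)
    img <- matrix(pmax(0, pmin(80, round(30 + rnorm(width * height,
                                                    sd = noiseSd)))),
                  width, height)
    area <- integer(nBlobs)
    for (i in seq_len(nBlobs)) {
      d <- .diskMask(width, height, placed$cx[i], placed$cy[i],
                     placed$radius[i])
      labels[d] <- i
      img[d] <- 200
      area[i] <- sum(d)
    }
    placed$area_px <- area
    list(image = newImageStack("Raw", img,
                               SpatialCalibration(dx = 0.5, dy = 0.5,
                                                  spatialUnit = "micron")),
         truth = placed, labels = labels)
  })
}

#' Synthetic moving spots with ground-truth tracks
#'
#' Solid spots advance with a constant per-frame displacement (all tracks
#' parallel, so inter-track spacing is constant) plus optional integer
#' jitter. The default displacement is the 3-4-5 construction (dx = 3,
#' dy = 4), giving exactly 5 px per step. The generation precondition
#' requires inter-track spacing > 4 * (step + 3 * noiseSigma).
#'
#' @param nSpots number of tracks.
#' @param nFrames number of frames.
#' @param step per-frame displacement: either a scalar magnitude (applied
#'   along x) or a c(dx, dy) vector.
#' @param noiseSigma standard deviation of integer positional jitter.
#' @param seed RNG seed.
#' @param spotRadius radius of each rendered spot.
#' @param spacing distance between adjacent track start points.
#' @return List: \code{image} (binary timeseries \code{ImageStack},
#'   frame interval 1), \code{truth} (data.frame track, frame, x, y of
#'   spot centres).
#' @export
makeMovingSpots <- function(nSpots = 2, nFrames = 3, step = c(3, 4),
                            noiseSigma = 0, seed = 1, spotRadius = 2,
                            spacing = NULL) {
  if (length(step) == 1) step <- c(step, 0)
  stepLen <- sqrt(sum(step^2))
  if (is.null(spacing)) spacing <- ceiling(4 * (stepLen + 3 * noiseSigma)) + 2
  if (spacing <= 4 * (stepLen + 3 * noiseSigma))
    stop("inter-track spacing must exceed 4 * (step + 3 * noiseSigma)")
  .withSeed(seed, {
    margin <- spotRadius + 3 + ceiling(3 * noiseSigma)
    width <- ceiling(margin * 2 + abs(step[1]) * (nFrames - 1)) + 6
    height <- ceiling(margin * 2 + abs(step[2]) * (nFrames - 1) +
                        spacing * (nSpots - 1)) + 6
    starts <- cbind(x = rep(margin, nSpots),
                    y = margin + spacing * (seq_len(nSpots) - 1))
    truth <- do.call(rbind, lapply(seq_len(nSpots), function(i) {
      jitter <- if (noiseSigma > 0)
        matrix(round(rnorm(2 * nFrames, sd = noiseSigma)), ncol = 2)
      else matrix(0L, nFrames, 2)
      data.frame(track = i, frame = seq_len(nFrames) - 1L,
                 x = starts[i, 1] + step[1] * (seq_len(nFrames) - 1) +
                   jitter[, 1],
                 y = starts[i, 2] + step[2] * (seq_len(nFrames) - 1) +
                   jitter[, 2])
    }))
    arr <- array(0, c(width, height, 1, 1, nFrames))
    for (k in seq_len(nrow(truth))) {
      d <- .diskMask(width, height, truth$x[k], truth$y[k], spotRadius)
      sl <- arr[, , 1, 1, truth$frame[k] + 1]
      sl[d] <- 255
      arr[, , 1, 1, truth$frame[k] + 1] <- sl
    }
    list(image = newImageStack("Spots", arr, SpatialCalibration(
           spatialUnit = "pixel", frameInterval = 1, timeUnit = "frame")),
         truth = truth)
  })
}

.drawHLine <- function(m, y, x0, x1) { m[(x0:x1) + 1, y + 1] <- 1; m }
.drawVLine <- function(m, x, y0, y1) { m[x + 1, (y0:y1) + 1] <- 1; m }

#' Synthetic 1-pixel-wide skeleton shapes with known topology
#'
#' Rasterises a named polyline shape and reports its true junction and
#' edge counts: "line" (0 junctions, 1 edge), "plus" (1, 4), "H" (2, 5)
#' and "grid" (a 2 x 2 lattice: 4 junctions, 12 edges).
#'
#' @param shape "line", "plus", "H" or "grid".
#' @param width,height image extent (the shape is sized to fit).
#' @return List: \code{image} (binary \code{ImageStack}), \code{truth}
#'   (list junctions, edges, terminalEdges — the number of edges touching
#'   exactly one junction).
#' @export
makeSkeletonImage <- function(shape = c("line", "plus", "H", "grid"),
                              width = 64, height = 64) {
  shape <- match.arg(shape)
  m <- matrix(0, width, height)
  cx <- width %/% 2; cy <- height %/% 2
  a <- 6L  # inset from the border
  truth <- switch(shape,
    line = {
      m <- .drawHLine(m, cy, a, width - a)
      list(junctions = 0L, edges = 1L, terminalEdges = 0L)
    },
    plus = {
      m <- .drawHLine(m, cy, a, width - a)
      m <- .drawVLine(m, cx, a, height - a)
      list(junctions = 1L, edges = 4L, terminalEdges = 4L)
    },
    H = {
      x1 <- width %/% 4; x2 <- 3 * (width %/% 4)
      m <- .drawVLine(m, x1, a, height - a)
      m <- .drawVLine(m, x2, a, height - a)
      m <- .drawHLine(m, cy, x1, x2)
      list(junctions = 2L, edges = 5L, terminalEdges = 4L)
    },
    grid = {
      x1 <- width %/% 3; x2 <- 2 * (width %/% 3)
      y1 <- height %/% 3; y2 <- 2 * (height %/% 3)
      m <- .drawVLine(m, x1, a, height - a)
      m <- .drawVLine(m, x2, a, height - a)
      m <- .drawHLine(m, y1, a, width - a)
      m <- .drawHLine(m, y2, a, width - a)
      list(junctions = 4L, edges = 12L, terminalEdges = 8L)
    })
  list(image = newImageStack(paste0("Skeleton_", shape), m * 255),
       truth = truth)
}

#' Morphology trio for the store-cost comparison
#'
#' Three binary masks at the same extent emulating the canonical
#' morphology classes used to compare coordinate stores: a single-pixel
#' "bacterium-like" object, a thin 1-px curve ("DNA-like" skeleton) and a
#' large solid ellipse ("nucleus-like" region).
#'
#' @param extent side length (power of two).
#' @return Named list of three logical matrices: \code{singlePixel},
#'   \code{thinCurve}, \code{solidEllipse}.
#' @export
makeMorphologyTrio <- function(extent = 256) {
  if (bitwAnd(extent, extent - 1L) != 0L)
    stop("extent must be a power of two")
  single <- matrix(FALSE, extent, extent)
  single[extent %/% 2, extent %/% 2] <- TRUE

  # thin sinuous filament, 1 px wide and 8-connected: the sine's slope is
  # kept below 1 so each x-step moves at most one pixel in y
  curve <- matrix(FALSE, extent, extent)
  xs <- seq(8L, extent - 8L)
  ys <- round(extent / 2 + (extent / 16) * sin((xs - 8) / extent * 4 * pi))
  curve[cbind(xs + 1, ys + 1)] <- TRUE

  ellipse <- matrix(FALSE, extent, extent)
  xsg <- matrix(seq_len(extent) - 1, extent, extent)
  ysg <- matrix(rep(seq_len(extent) - 1, each = extent), extent, extent)
  cx <- extent / 2; cy <- extent / 2
  ellipse[((xsg - cx) / (extent * 0.39))^2 +
            ((ysg - cy) / (extent * 0.27))^2 <= 1] <- TRUE

  list(singlePixel = single, thinCurve = curve, solidEllipse = ellipse)
}

#' Random object-like binary mask
#'
#' Union of randomly placed solid spheres and boxes plus a sprinkle of
#' isolated voxels — the morphology mix used for store-equivalence
#' checks.
#'
#' @param width,height,nSlices mask extent.
#' @param nShapes number of solid shapes.
#' @param seed RNG seed.
#' @return Logical 3D array (x, y, z).
#' @export
makeRandomMask <- function(width = 64, height = 64, nSlices = 1,
                           nShapes = 4, seed = 1) {
  .withSeed(seed, {
    m <- array(FALSE, c(width, height, nSlices))
    xs <- array(rep(seq_len(width) - 1, times = height * nSlices), dim(m))
    ys <- array(rep(rep(seq_len(height) - 1, each = width), times = nSlices),
                dim(m))
    zs <- array(rep(seq_len(nSlices) - 1, each = width * height), dim(m))
    for (i in seq_len(nShapes)) {
      if (runif(1) < 0.5) {
        r <- runif(1, 2, max(3, min(width, height) / 5))
        cx <- runif(1, 0, width - 1); cy <- runif(1, 0, height - 1)
        cz <- runif(1, 0, nSlices - 1)
        zscale <- if (nSlices > 1) 1 else Inf
        m <- m | ((xs - cx)^2 + (ys - cy)^2 +
                    (if (nSlices > 1) (zs - cz)^2 else 0) <= r^2)
      } else {
        w <- sample.int(max(2, width %/% 4), 1) + 1
        h <- sample.int(max(2, height %/% 4), 1) + 1
        x0 <- sample.int(width, 1) - 1; y0 <- sample.int(height, 1) - 1
        z0 <- sample.int(nSlices, 1) - 1
        zd <- if (nSlices > 1) sample.int(nSlices, 1) else 1
        m <- m | (xs >= x0 & xs <= x0 + w & ys >= y0 & ys <= y0 + h &
                    zs >= z0 & zs <= z0 + zd - 1)
      }
    }
    npix <- max(1L, round(prod(dim(m)) * 0.001))
    m[sample.int(prod(dim(m)), npix)] <- TRUE
    m
  })
}
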