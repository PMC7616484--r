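#' Coordinate stores: interchangeable voxel storage for objects
#'
#' The foreground voxels of one object can be held as an explicit list of
#' XYZ pixel locations (a pointlist), as one quadtree per occupied z-slice,
#' or as a single 3D octree. Quadtrees/octrees recursively subdivide the
#' (power-of-two padded) extent into quadrants/octants, stopping as soon as
#' a node is uniformly foreground or uniformly background, so large solid
#' regions collapse to few nodes while pixel-scale detail forces
#' subdivision to the pixel level. All three stores satisfy the same access
#' contract (\code{\link{storeVoxels}}, \code{\link{storeQuery}},
#' \code{\link{storeSize}}, \code{\link{storeToMask}},
#' \code{\link{storeCost}}) and are interchangeable downstream; only the
#' abstract memory cost differs.
#'
#' Coordinates are 0-based integers. Trees are always maximally merged: no
#' subdivided node has four (eight) uniform children of equal state.
#'
#' @name CoordinateStore-class
#' @aliases CoordinateStore
#' @export
setClass("CoordinateStore", representation("VIRTUAL"))

#' @rdname CoordinateStore-class
#' @export
setClass("PointListStore", contains = "CoordinateStore",
  representation(coords = "matrix"),
  prototype(coords = matrix(integer(0), ncol = 3,
                            dimnames = list(NULL, c("x", "y", "z")))),
  validity = function(object) {
    m <- object@coords
    if (ncol(m) != 3) return("coords must have 3 columns (x, y, z)")
    if (nrow(m) && any(m < 0)) return("coordinates must be >= 0")
    if (anyDuplicated(m)) return("duplicate voxels are not permitted")
    TRUE
  }
)

#' @rdname CoordinateStore-class
#' @export
setClass("QuadtreeStore", contains = "CoordinateStore",
  representation(trees = "list", rootSize = "integer", extent = "integer"),
  prototype(trees = list(), rootSize = 1L, extent = c(1L, 1L, 1L)),
  validity = function(object) {
    if (length(object@extent) != 3) return("extent must be (width, height, nSlices)")
    if (bitwAnd(object@rootSize, object@rootSize - 1L) != 0L)
      return("rootSize must be a power of two")
    TRUE
  }
)

#' @rdname CoordinateStore-class
#' @export
setClass("OctreeStore", contains = "CoordinateStore",
  representation(tree = "list", rootSize = "integer", extent = "integer"),
  prototype(tree = list(state = "bg"), rootSize = 1L, extent = c(1L, 1L, 1L)),
  validity = function(object) {
    if (length(object@extent) != 3) return("extent must be (width, height, nSlices)")
    if (bitwAnd(object@rootSize, object@rootSize - 1L) != 0L)
      return("rootSize must be a power of two")
    TRUE
  }
)

.canonicalVoxelOrder <- function(m) {
  if (nrow(m) == 0) return(m)
  m[order(m[, 3], m[, 2], m[, 1]), , drop = FALSE]
}

.voxelMatrix <- function(m) {
  m <- matrix(as.integer(m), ncol = 3)
  colnames(m) <- c("x", "y", "z")
  .canonicalVoxelOrder(unique(m))
}

.pow2Above <- function(n) {
  s <- 1L
  while (s < n) s <- s * 2L
  s
}

# summed-area table of a logical matrix (x by y); rect sums in O(1)
.sat2 <- function(m) {
  w <- nrow(m); h <- ncol(m)
  cs <- apply(m, 2, cumsum)
  if (h > 1) cs <- t(apply(cs, 1, cumsum))
  S <- matrix(0, w + 1, h + 1)
  S[2:(w + 1), 2:(h + 1)] <- cs
  S
}

.rect2 <- function(S, x0, y0, size, w, h) {
  x1 <- min(x0 + size, w); y1 <- min(y0 + size, h)
  if (x0 >= w || y0 >= h || x1 <= x0 || y1 <= y0) return(0)
  S[x1 + 1, y1 + 1] - S[x0 + 1, y1 + 1] - S[x1 + 1, y0 + 1] + S[x0 + 1, y0 + 1]
}

.sat3 <- function(a) {
  d <- dim(a)
  cs <- array(as.numeric(a), d)
  if (d[1] > 1) for (i in 2:d[1]) cs[i, , ] <- cs[i, , ] + cs[i - 1, , ]
  if (d[2] > 1) for (j in 2:d[2]) cs[, j, ] <- cs[, j, ] + cs[, j - 1, ]
  if (d[3] > 1) for (k in 2:d[3]) cs[, , k] <- cs[, , k] + cs[, , k - 1]
  S <- array(0, d + 1L)
  S[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cs
  S
}

.rect3 <- function(S, x0, y0, z0, size, w, h, n) {
  x1 <- min(x0 + size, w); y1 <- min(y0 + size, h); z1 <- min(z0 + size, n)
  if (x0 >= w || y0 >= h || z0 >= n || x1 <= x0 || y1 <= y0 || z1 <= z0) return(0)
  S[x1 + 1, y1 + 1, z1 + 1] - S[x0 + 1, y1 + 1, z1 + 1] -
    S[x1 + 1, y0 + 1, z1 + 1] - S[x1 + 1, y1 + 1, z0 + 1] +
    S[x0 + 1, y0 + 1, z1 + 1] + S[x0 + 1, y1 + 1, z0 + 1] +
    S[x1 + 1, y0 + 1, z0 + 1] - S[x0 + 1, y0 + 1, z0 + 1]
}

.leaf <- function(state) list(state = state)

.buildQuad <- function(S, x0, y0, size, w, h) {
  cnt <- .rect2(S, x0, y0, size, w, h)
  if (cnt == 0) return(.leaf("bg"))
  if (cnt == size * size) return(.leaf("fg"))
  half <- size %/% 2L
  list(state = "div", kids = list(
    .buildQuad(S, x0, y0, half, w, h),
    .buildQuad(S, x0 + half, y0, half, w, h),
    .buildQuad(S, x0, y0 + half, half, w, h),
    .buildQuad(S, x0 + half, y0 + half, half, w, h)
  ))
}

.buildOct <- function(S, x0, y0, z0, size, w, h, n) {
  cnt <- .rect3(S, x0, y0, z0, size, w, h, n)
  if (cnt == 0) return(.leaf("bg"))
  if (cnt == size^3) return(.leaf("fg"))
  half <- size %/% 2L
  kids <- vector("list", 8)
  i <- 1
  for (dz in c(0L, half)) for (dy in c(0L, half)) for (dx in c(0L, half)) {
    kids[[i]] <- .buildOct(S, x0 + dx, y0 + dy, z0 + dz, half, w, h, n)
    i <- i + 1
  }
  list(state = "div", kids = kids)
}

.normaliseMask <- function(mask) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  if (length(dim(mask)) != 3)
    stop("mask must be a 2D matrix or 3D array (x, y, z)")
  mask <- mask != 0
  storage.mode(mask) <- "logical"
  mask
}

#' Build a coordinate store from a binary mask
#'
#' @param mask 2D matrix or 3D array indexed (x, y, z); non-zero cells are
#'   foreground. An all-background mask yields a valid empty store.
#' @param method one of \code{"pointlist"}, \code{"quadtree"},
#'   \code{"octree"}. Any other value is a configuration error.
#' @return A \code{CoordinateStore}. Quadtree stores hold one tree per
#'   occupied z-slice; octree stores a single 3D tree. The padded area
#'   beyond the mask extent (root size is the smallest covering power of
#'   two) is treated as uniform background and never emitted as
#'   coordinates.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
#' s <- storeFromMask(m, "quadtree")
#' storeSize(s)
#' @export
storeFromMask <- function(mask, method = c("pointlist", "quadtree", "octree")) {
  method <- match.arg(method)
  mask <- .normaliseMask(mask)
  d <- dim(mask)
  if (any(d < 1)) stop("mask dimensions must be >= 1 in each axis")
  if (method == "pointlist") {
    idx <- which(mask, arr.ind = TRUE)
    return(new("PointListStore", coords = .voxelMatrix(idx - 1L)))
  }
  if (method == "quadtree") {
    root <- .pow2Above(max(d[1], d[2]))
    trees <- list()
    for (z in seq_len(d[3])) {
      slice <- mask[, , z, drop = TRUE]
      if (!is.matrix(slice)) slice <- matrix(slice, d[1], d[2])
      if (!any(slice)) next
      trees[[as.character(z - 1L)]] <-
        .buildQuad(.sat2(slice), 0L, 0L, root, d[1], d[2])
    }
    return(new("QuadtreeStore", trees = trees, rootSize = root,
               extent = as.integer(d)))
  }
  root <- .pow2Above(max(d))
  tree <- if (any(mask)) .buildOct(.sat3(mask), 0L, 0L, 0L, root,
                                   d[1], d[2], d[3]) else .leaf("bg")
  new("OctreeStore", tree = tree, rootSize = root, extent = as.integer(d))
}

## ---- access contract ----

#' Access contract shared by all coordinate stores
#'
#' \code{storeVoxels} returns the voxel set as an n x 3 integer matrix in
#' canonical (z, y, x) order; \code{storeSize} the foreground voxel count;
#' \code{storeQuery} membership of one voxel; \code{storeToMask} a dense
#' binary array; \code{storeCost} the abstract memory cost;
#' \code{storeAddVoxel} inserts a voxel (tree stores re-merge affected
#' ancestors so maximal merging always holds); \code{storeMethod} the
#' method name.
#'
#' The abstract cost model is 3 units per stored voxel for pointlists
#' (x, y, z) and 4 units per tree node (corner, size, state); it is
#' hardware-independent and preserves the morphology-dependent orderings of
#' the underlying byte costs (pointlists win for single pixels and
#' skeletons; trees win for large solid regions). Users needing bytes can
#' rescale.
#'
#' @param store a \code{CoordinateStore}.
#' @param x,y,z 0-based voxel coordinate.
#' @param width,height,nSlices output extents for \code{storeToMask};
#'   default to the store's own extent where known. Extents smaller than a
#'   stored coordinate are an error.
#' @name store-contract
NULL

#' @rdname store-contract
#' @export
setGeneric("storeVoxels", function(store) standardGeneric("storeVoxels"))
#' @rdname store-contract
#' @export
setGeneric("storeSize", function(store) standardGeneric("storeSize"))
#' @rdname store-contract
#' @export
setGeneric("storeQuery", function(store, x, y, z) standardGeneric("storeQuery"))
#' @rdname store-contract
#' @export
setGeneric("storeToMask", function(store, width = NULL, height = NULL,
                                   nSlices = NULL) standardGeneric("storeToMask"))
#' @rdname store-contract
#' @export
setGeneric("storeCost", function(store) standardGeneric("storeCost"))
#' @rdname store-contract
#' @export
setGeneric("storeAddVoxel", function(store, x, y, z) standardGeneric("storeAddVoxel"))
#' @rdname store-contract
#' @export
setGeneric("storeMethod", function(store) standardGeneric("storeMethod"))

setMethod("storeMethod", "PointListStore", function(store) "pointlist")
setMethod("storeMethod", "QuadtreeStore", function(store) "quadtree")
setMethod("storeMethod", "OctreeStore", function(store) "octree")

## pointlist methods

setMethod("storeVoxels", "PointListStore", function(store)
  .canonicalVoxelOrder(store@coords))

setMethod("storeSize", "PointListStore", function(store) nrow(store@coords))

setMethod("storeQuery", "PointListStore", function(store, x, y, z) {
  m <- store@coords
  any(m[, 1] == x & m[, 2] == y & m[, 3] == z)
})

setMethod("storeAddVoxel", "PointListStore", function(store, x, y, z) {
  if (storeQuery(store, x, y, z)) return(store)
  new("PointListStore",
      coords = .canonicalVoxelOrder(rbind(store@coords,
                                          c(as.integer(x), as.integer(y),
                                            as.integer(z)))))
})

## tree walking helpers

.quadLeafVoxels <- function(node, x0, y0, size, z, acc) {
  if (node$state == "fg") {
    acc[[length(acc) + 1]] <- cbind(
      rep(x0:(x0 + size - 1L), times = size),
      rep(y0:(y0 + size - 1L), each = size),
      z)
    return(acc)
  }
  if (node$state == "bg") return(acc)
  half <- size %/% 2L
  acc <- .quadLeafVoxels(node$kids[[1]], x0, y0, half, z, acc)
  acc <- .quadLeafVoxels(node$kids[[2]], x0 + half, y0, half, z, acc)
  acc <- .quadLeafVoxels(node$kids[[3]], x0, y0 + half, half, z, acc)
  .quadLeafVoxels(node$kids[[4]], x0 + half, y0 + half, half, z, acc)
}

.octLeafVoxels <- function(node, x0, y0, z0, size, acc) {
  if (node$state == "fg") {
    g <- expand.grid(x = x0:(x0 + size - 1L), y = y0:(y0 + size - 1L),
                     z = z0:(z0 + size - 1L))
    acc[[length(acc) + 1]] <- as.matrix(g)
    return(acc)
  }
  if (node$state == "bg") return(acc)
  half <- size %/% 2L
  i <- 1
  for (dz in c(0L, half)) for (dy in c(0L, half)) for (dx in c(0L, half)) {
    acc <- .octLeafVoxels(node$kids[[i]], x0 + dx, y0 + dy, z0 + dz, half, acc)
    i <- i + 1
  }
  acc
}

setMethod("storeVoxels", "QuadtreeStore", function(store) {
  acc <- list()
  for (zc in names(store@trees)) {
    acc <- .quadLeafVoxels(store@trees[[zc]], 0L, 0L, store@rootSize,
                           as.integer(zc), acc)
  }
  if (!length(acc))
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  .voxelMatrix(do.call(rbind, acc))
})

setMethod("storeVoxels", "OctreeStore", function(store) {
  acc <- .octLeafVoxels(store@tree, 0L, 0L, 0L, store@rootSize, list())
  if (!length(acc))
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  .voxelMatrix(do.call(rbind, acc))
})

.treeCounts <- function(node) {
  if (node$state != "div") {
    return(c(total = 1L, leaves = 1L,
             voxels = NA_integer_))  # voxel count needs size; done separately
  }
  k <- vapply(node$kids, .treeCounts, c(total = 0L, leaves = 0L, voxels = 0L))
  c(total = 1L + sum(k["total", ]), leaves = sum(k["leaves", ]), voxels = 0L)
}

.quadCount <- function(node, size) {
  if (node$state == "fg") return(size * size)
  if (node$state == "bg") return(0)
  half <- size %/% 2L
  sum(vapply(node$kids, .quadCount, numeric(1), size = half))
}

.octCount <- function(node, size) {
  if (node$state == "fg") return(size^3)
  if (node$state == "bg") return(0)
  half <- size %/% 2L
  sum(vapply(node$kids, .octCount, numeric(1), size = half))
}

setMethod("storeSize", "QuadtreeStore", function(store) {
  s <- 0
  for (tr in store@trees) s <- s + .quadCount(tr, store@rootSize)
  as.integer(s)
})

setMethod("storeSize", "OctreeStore", function(store)
  as.integer(.octCount(store@tree, store@rootSize)))

.treeQuery2 <- function(node, x, y, x0, y0, size) {
  while (node$state == "div") {
    half <- size %/% 2L
    ix <- (x >= x0 + half); iy <- (y >= y0 + half)
    node <- node$kids[[1L + ix + 2L * iy]]
    if (ix) x0 <- x0 + half
    if (iy) y0 <- y0 + half
    size <- half
  }
  node$state == "fg"
}

setMethod("storeQuery", "QuadtreeStore", function(store, x, y, z) {
  tr <- store@trees[[as.character(as.integer(z))]]
  if (is.null(tr)) return(FALSE)
  if (x < 0 || y < 0 || x >= store@rootSize || y >= store@rootSize) return(FALSE)
  .treeQuery2(tr, x, y, 0L, 0L, store@rootSize)
})

setMethod("storeQuery", "OctreeStore", function(store, x, y, z) {
  if (any(c(x, y, z) < 0) || any(c(x, y, z) >= store@rootSize)) return(FALSE)
  node <- store@tree; x0 <- y0 <- z0 <- 0L; size <- store@rootSize
  while (node$state == "div") {
    half <- size %/% 2L
    ix <- (x >= x0 + half); iy <- (y >= y0 + half); iz <- (z >= z0 + half)
    node <- node$kids[[1L + ix + 2L * iy + 4L * iz]]
    if (ix) x0 <- x0 + half
    if (iy) y0 <- y0 + half
    if (iz) z0 <- z0 + half
    size <- half
  }
  node$state == "fg"
})

## mask rendering

setMethod("storeToMask", "CoordinateStore",
          function(store, width = NULL, height = NULL, nSlices = NULL) {
  v <- storeVoxels(store)
  ext <- if (is(store, "PointListStore")) {
    if (nrow(v)) apply(v, 2, max) + 1L else c(1L, 1L, 1L)
  } else store@extent
  width <- if (is.null(width)) ext[1] else as.integer(width)
  height <- if (is.null(height)) ext[2] else as.integer(height)
  nSlices <- if (is.null(nSlices)) ext[3] else as.integer(nSlices)
  if (nrow(v) && (max(v[, 1]) >= width || max(v[, 2]) >= height ||
                  max(v[, 3]) >= nSlices))
    stop("requested extents do not cover all stored voxels")
  m <- array(FALSE, c(width, height, nSlices))
  if (nrow(v)) m[v[, 1] + 1L + width * (v[, 2] + height * v[, 3])] <- TRUE
  m
})

## cost model

setMethod("storeCost", "PointListStore", function(store)
  3L * nrow(store@coords))

setMethod("storeCost", "QuadtreeStore", function(store) {
  n <- 0L
  for (tr in store@trees) n <- n + .treeCounts(tr)["total"]
  unname(4L * n)
})

setMethod("storeCost", "OctreeStore", function(store)
  unname(4L * .treeCounts(store@tree)["total"]))

#' Node and leaf counts of a tree-backed store
#'
#' @param store a \code{QuadtreeStore} or \code{OctreeStore}.
#' @return Named integer vector with elements \code{total} and
#'   \code{leaves}; quadtree counts are summed over slices.
#' @export
storeNodeCounts <- function(store) {
  if (is(store, "QuadtreeStore")) {
    tot <- 0L; lv <- 0L
    for (tr in store@trees) {
      k <- .treeCounts(tr); tot <- tot + k["total"]; lv <- lv + k["leaves"]
    }
    return(c(total = unname(tot), leaves = unname(lv)))
  }
  if (is(store, "OctreeStore")) {
    k <- .treeCounts(store@tree)
    return(c(total = unname(k["total"]), leaves = unname(k["leaves"])))
  }
  stop("node counts are defined for tree-backed stores only")
}

## insertion with ancestor re-merging

.mergeIfUniform <- function(node) {
  if (node$state != "div") return(node)
  states <- vapply(node$kids, function(k) k$state, "")
  if (all(states == "fg")) return(.leaf("fg"))
  if (all(states == "bg")) return(.leaf("bg"))
  node
}

.quadInsert <- function(node, x, y, x0, y0, size) {
  if (node$state == "fg") return(node)
  if (size == 1L) return(.leaf("fg"))
  if (node$state == "bg")
    node <- list(state = "div", kids = list(.leaf("bg"), .leaf("bg"),
                                            .leaf("bg"), .leaf("bg")))
  half <- size %/% 2L
  ix <- (x >= x0 + half); iy <- (y >= y0 + half)
  i <- 1L + ix + 2L * iy
  node$kids[[i]] <- .quadInsert(node$kids[[i]], x, y,
                                x0 + if (ix) half else 0L,
                                y0 + if (iy) half else 0L, half)
  .mergeIfUniform(node)
}

.octInsert <- function(node, x, y, z, x0, y0, z0, size) {
  if (node$state == "fg") return(node)
  if (size == 1L) return(.leaf("fg"))
  if (node$state == "bg")
    node <- list(state = "div", kids = replicate(8, .leaf("bg"),
                                                 simplify = FALSE))
  half <- size %/% 2L
  ix <- (x >= x0 + half); iy <- (y >= y0 + half); iz <- (z >= z0 + half)
  i <- 1L + ix + 2L * iy + 4L * iz
  node$kids[[i]] <- .octInsert(node$kids[[i]], x, y, z,
                               x0 + if (ix) half else 0L,
                               y0 + if (iy) half else 0L,
                               z0 + if (iz) half else 0L, half)
  .mergeIfUniform(node)
}

setMethod("storeAddVoxel", "QuadtreeStore", function(store, x, y, z) {
  if (x < 0 || y < 0 || x >= store@rootSize || y >= store@rootSize)
    stop("voxel outside the quadtree root extent")
  zc <- as.character(as.integer(z))
  tr <- store@trees[[zc]]
  if (is.null(tr)) tr <- .leaf("bg")
  store@trees[[zc]] <- .quadInsert(tr, as.integer(x), as.integer(y),
                                   0L, 0L, store@rootSize)
  ext <- store@extent
  store@extent <- as.integer(pmax(ext, c(x + 1L, y + 1L, z + 1L)))
  store
})

setMethod("storeAddVoxel", "OctreeStore", function(store, x, y, z) {
  if (any(c(x, y, z) < 0) || any(c(x, y, z) >= store@rootSize))
    stop("voxel outside the octree root extent")
  store@tree <- .octInsert(store@tree, as.integer(x), as.integer(y),
                           as.integer(z), 0L, 0L, 0L, store@rootSize)
  store@extent <- as.integer(pmax(store@extent, c(x + 1L, y + 1L, z + 1L)))
  store
})

#' Audit maximal merging of a tree store
#'
#' Walks every tree and checks that no subdivided node has all-uniform,
#' same-state children. Used by the test suite; exported because it is a
#' cheap structural sanity check after manual insertions.
#'
#' @param store a tree-backed \code{CoordinateStore}.
#' @return TRUE, or a character description of the first violation.
#' @export
storeIsMaximallyMerged <- function(store) {
  walk <- function(node) {
    if (node$state != "div") return(TRUE)
    states <- vapply(node$kids, function(k) k$state, "")
    if (all(states == states[1]) && states[1] != "div")
      return("subdivided node with uniform same-state children")
    for (k in node$kids) {
      r <- walk(k)
      if (!isTRUE(r)) return(r)
    }
    TRUE
  }
  if (is(store, "QuadtreeStore")) {
    for (tr in store@trees) {
      r <- walk(tr)
      if (!isTRUE(r)) return(r)
    }
    return(TRUE)
  }
  if (is(store, "OctreeStore")) return(walk(store@tree))
  TRUE
}

#' Create an empty store
#'
#' Empty stores back coordinate-less linking objects such as tracks.
#' @return An empty \code{PointListStore}.
#' @export
emptyStore <- function() new("PointListStore")

setMethod("show", "PointListStore", function(object)
  cat(sprintf("PointListStore with %d voxels (cost %d units)\n",
              storeSize(object), storeCost(object))))
setMethod("show", "QuadtreeStore", function(object)
  cat(sprintf("QuadtreeStore: %d voxels, %d slices, root %d, cost %d units\n",
              storeSize(object), length(object@trees), object@rootSize,
              storeCost(object))))
setMethod("show", "OctreeStore", function(object)
  cat(sprintf("OctreeStore: %d voxels, root %d, cost %d units\n",
              storeSize(object), object@rootSize, storeCost(object))))
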