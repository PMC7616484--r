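#' Decompose a binary image into skeleton edges and junctions
#'
#' The input is skeletonised per slice and timepoint by 2D topological
#' thinning (Zhang-Suen), then partitioned: skeleton pixels with more than
#' two 8-neighbours on the skeleton are junction pixels (adjacent junction
#' pixels merge into one Junction object, 8-connectivity); the remaining
#' skeleton pixels group into Edge objects (8-connectivity). An edge and a
#' junction are assigned a partner relationship iff any of their pixels are
#' 8-adjacent — so in well-formed skeletons an edge relates to up to two
#' junctions while a junction relates to several edges. Both sets use
#' pointlist coordinate stores (the most efficient method for 1-px-wide
#' morphologies). Junction pixels plus edge pixels partition the skeleton.
#'
#' @param img binary single-channel \code{\link{ImageStack}}.
#' @param edgeName,junctionName class names for the two new sets.
#' @return List with elements \code{edges} and \code{junctions}
#'   (\code{\link{ObjectSet}}s with partner links established).
#' @export
skeletonDecompose <- function(img, edgeName = "Edges",
                              junctionName = "Junctions") {
  if (!isBinaryImage(img)) stop("skeleton_decompose requires a binary image")
  d <- dim(img$data)
  if (d[3] != 1L) stop("skeleton_decompose requires a single-channel image")
  edges <- ObjectSet$new(className = edgeName, calibration = img$calibration)
  junctions <- ObjectSet$new(className = junctionName,
                             calibration = img$calibration)
  for (t in seq_len(d[5])) for (z in seq_len(d[4])) {
    sk <- .thin2D(img$data[, , 1, z, t])
    if (!any(sk > 0)) next
    nc <- .neighbourCount2D(sk)
    juncMask <- sk == 1L & nc > 2L
    edgeMask <- sk == 1L & nc <= 2L
    jlab <- labelComponents(array(juncMask, c(d[1], d[2], 1L)), inPlane = 8L)
    elab <- labelComponents(array(edgeMask, c(d[1], d[2], 1L)), inPlane = 8L)
    jlab <- jlab[, , 1]; elab <- elab[, , 1]
    mkObjs <- function(lab, set) {
      k <- max(lab)
      out <- vector("list", k)
      if (k == 0L) return(out)
      idx <- which(lab > 0L, arr.ind = TRUE)
      labs <- lab[lab > 0L]
      for (i in seq_len(k)) {
        px <- idx[labs == i, , drop = FALSE]
        coords <- cbind(px[, 1] - 1L, px[, 2] - 1L, z - 1L)
        out[[i]] <- set$newObj(
          timepoint = t - 1L,
          store = new("PointListStore", coords = .voxelMatrix(coords)))
      }
      out
    }
    jObjs <- mkObjs(jlab, junctions)
    eObjs <- mkObjs(elab, edges)
    # partner an edge with a junction iff any pixel pair is 8-adjacent
    if (length(jObjs) && length(eObjs)) {
      jpx <- which(jlab > 0L, arr.ind = TRUE)
      seen <- character(0)
      for (r in seq_len(nrow(jpx))) {
        jid <- jlab[jpx[r, 1], jpx[r, 2]]
        for (dx in -1:1) for (dy in -1:1) {
          if (dx == 0 && dy == 0) next
          x <- jpx[r, 1] + dx; y <- jpx[r, 2] + dy
          if (x < 1 || y < 1 || x > d[1] || y > d[2]) next
          eid <- elab[x, y]
          if (eid > 0L) {
            key <- paste(jid, eid)
            if (!(key %in% seen)) {
              assignPartners(eObjs[[eid]], jObjs[[jid]])
              seen <- c(seen, key)
            }
          }
        }
      }
    }
  }
  list(edges = edges, junctions = junctions)
}

#' Prune terminal skeleton edges
#'
#' Removes every edge partnered with exactly one junction — the open
#' branches of the skeleton. Edges with zero partners (isolated lines) or
#' two partners (junction-to-junction spans) are retained. Junction
#' partner lists are updated by the removal.
#'
#' @param edges,junctions the sets produced by
#'   \code{\link{skeletonDecompose}}.
#' @return \code{edges}, invisibly (filtered in place).
#' @export
pruneTerminalEdges <- function(edges, junctions) {
  for (o in edges$objects()) {
    nPartners <- length(getPartners(o, junctions$className))
    if (nPartners == 1L) edges$removeObj(o$id)
  }
  invisible(edges)
}
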