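#' @importFrom igraph graph_from_edgelist components
NULL

# neighbourhood offsets for a given connectivity; only "positive" half-space
# offsets are needed when building an undirected adjacency
.connOffsets <- function(inPlane = 4L, volumetric = 0L) {
  offs <- list(c(1L, 0L, 0L), c(0L, 1L, 0L))
  if (inPlane == 8L) offs <- c(offs, list(c(1L, 1L, 0L), c(1L, -1L, 0L)))
  if (volumetric == 6L) offs <- c(offs, list(c(0L, 0L, 1L)))
  if (volumetric == 26L) {
    offs <- c(offs, list(c(0L, 0L, 1L)))
    for (dx in -1L:1L) for (dy in -1L:1L) {
      if (dx == 0L && dy == 0L) next
      offs <- c(offs, list(c(dx, dy, 1L)))
    }
  }
  offs
}

#' Label connected components of a 3D binary mask
#'
#' Components are computed per the requested in-plane (4 or 8) and
#' volumetric (6 or 26, or 0 to keep slices independent) connectivity, by
#' building the voxel adjacency graph and taking its connected components.
#' Labels are assigned in scan order (first-encountered voxel in x-fastest
#' order gets label 1), so results are deterministic.
#'
#' @param mask 3D logical/numeric array (x, y, z).
#' @param inPlane 4 or 8.
#' @param volumetric 0 (slices independent), 6 or 26.
#' @return Integer array of the same dimension; 0 = background.
#' @export
labelComponents <- function(mask, inPlane = 4L, volumetric = 0L) {
  mask <- .normaliseMask(mask)
  d <- dim(mask)
  if (d[3] == 1L) volumetric <- 0L
  fg <- which(mask)
  out <- array(0L, d)
  if (!length(fg)) return(out)
  rank <- integer(prod(d))
  rank[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)
  edges <- list()
  for (off in .connOffsets(inPlane, volumetric)) {
    nb <- sweep(coords, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + d[1] * ((nb[ok, 2] - 1L) + d[2] * (nb[ok, 3] - 1L))
    hit <- mask[lin]
    if (!any(hit)) next
    edges[[length(edges) + 1]] <-
      cbind(rank[fg[ok]][hit], rank[lin[hit]])
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    # isolated voxels may be missing from the edge list
    nv <- length(fg)
    if (igraph::vcount(g) < nv)
      g <- igraph::add_vertices(g, nv - igraph::vcount(g))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(fg)
  }
  # relabel in scan order of first appearance
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  out[fg] <- relab[comp]
  out
}

#' Otsu threshold of an intensity sample
#'
#' Computes the cut maximising the between-class variance over a 256-bin
#' histogram of min-max scaled intensities, the canonical automatic
#' threshold. Foreground is defined as strictly above the returned value.
#'
#' @param values numeric vector of intensities.
#' @return Threshold on the original intensity scale, or NA for a constant
#'   input (degenerate histogram — callers emit an all-background result
#'   with a warning).
#' @export
otsuThreshold <- function(values) {
  values <- values[is.finite(values)]
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(NA_real_)
  bins <- pmin(floor((values - lo) / (hi - lo) * 256), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  muT <- mu[256]
  denom <- omega * (1 - omega)
  sigmaB <- ifelse(denom > 0, (muT * omega - mu)^2 / denom, -Inf)
  k <- which.max(sigmaB[-256])  # cut after bin k-1; lowest k wins ties
  lo + (k - 0.5) / 256 * (hi - lo)
}

# 8-neighbour count of every foreground pixel (2D, matrix x by y)
.neighbourCount2D <- function(m) {
  w <- nrow(m); h <- ncol(m)
  p <- matrix(0L, w + 2, h + 2)
  p[2:(w + 1), 2:(h + 1)] <- m
  n <- matrix(0L, w, h)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    n <- n + p[(2 + dx):(w + 1 + dx), (2 + dy):(h + 1 + dy)]
  }
  n
}

# Zhang-Suen thinning of a 2D binary matrix (x by y) to a 1-px skeleton
.thin2D <- function(m) {
  m <- (m != 0) + 0L
  w <- nrow(m); h <- ncol(m)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- matrix(0L, w + 2, h + 2)
      p[2:(w + 1), 2:(h + 1)] <- m
      sh <- function(dx, dy) p[(2 + dx):(w + 1 + dx), (2 + dy):(h + 1 + dy)]
      # neighbours clockwise from north: P2..P9 (x right, y down convention)
      P2 <- sh(0, -1); P3 <- sh(1, -1); P4 <- sh(1, 0); P5 <- sh(1, 1)
      P6 <- sh(0, 1); P7 <- sh(-1, 1); P8 <- sh(-1, 0); P9 <- sh(-1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- matrix(0L, w, h)
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (phase == 1) {
        c1 <- P2 * P4 * P6; c2 <- P4 * P6 * P8
      } else {
        c1 <- P2 * P4 * P8; c2 <- P2 * P6 * P8
      }
      del <- m == 1L & B >= 2 & B <= 6 & A == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}
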