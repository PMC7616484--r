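# Independent oracles used across the suite. These deliberately do not
# share code with the package: subdivision is re-derived by brute force on
# the dense grid, assignment by exhaustive enumeration, Otsu by exhaustive
# search over cut points.

# brute-force quadtree subdivision of one slice (padding = background);
# returns c(total nodes, leaves), merging-free recursion: a region is a
# leaf iff it is uniform (foreground cells filling it entirely, or no
# foreground at all)
quadCountOracle <- function(slice) {
  w <- nrow(slice); h <- ncol(slice)
  root <- 2^ceiling(log2(max(w, h)))
  rec <- function(x0, y0, s) {
    xs <- (x0 + 1):min(x0 + s, w)
    ys <- (y0 + 1):min(y0 + s, h)
    inside <- x0 < w && y0 < h
    cnt <- if (inside) sum(slice[xs, ys, drop = FALSE]) else 0
    if (cnt == 0) return(c(1L, 1L))
    if (cnt == s * s) return(c(1L, 1L))
    half <- s / 2
    k <- rec(x0, y0, half) + rec(x0 + half, y0, half) +
      rec(x0, y0 + half, half) + rec(x0 + half, y0 + half, half)
    c(1L + k[1], k[2])
  }
  rec(0, 0, root)
}

# brute-force octree subdivision of a 3D grid
octCountOracle <- function(grid) {
  d <- dim(grid)
  root <- 2^ceiling(log2(max(d)))
  rec <- function(x0, y0, z0, s) {
    inside <- x0 < d[1] && y0 < d[2] && z0 < d[3]
    cnt <- if (inside)
      sum(grid[(x0 + 1):min(x0 + s, d[1]),
               (y0 + 1):min(y0 + s, d[2]),
               (z0 + 1):min(z0 + s, d[3]), drop = FALSE]) else 0
    if (cnt == 0 || cnt == s^3) return(c(1L, 1L))
    half <- s / 2
    k <- c(0L, 0L)
    for (dz in c(0, half)) for (dy in c(0, half)) for (dx in c(0, half))
      k <- k + rec(x0 + dx, y0 + dy, z0 + dz, half)
    c(1L + k[1], k[2])
  }
  rec(0, 0, 0, root)
}

# exhaustive frame-linking oracle: minimise sum of squared distances over
# all injective link sets with the Jaqaman objective (alt cost per
# unlinked object on either side)
linkOracle <- function(ca, cb, maxDist, altFactor = 1.05) {
  n <- nrow(ca); m <- nrow(cb)
  d2 <- outer(seq_len(n), seq_len(m), Vectorize(function(i, j)
    sum((ca[i, ] - cb[j, ])^2)))
  adm <- which(d2 <= maxDist^2, arr.ind = TRUE)
  if (!nrow(adm)) return(cbind(integer(0), integer(0)))
  alt <- altFactor * max(d2[adm])
  eps <- min(d2[adm])
  best <- NULL; bestCost <- Inf
  subsets <- seq_len(2^nrow(adm)) - 1L
  for (s in subsets) {
    pick <- which(bitwAnd(s, 2^(seq_len(nrow(adm)) - 1)) > 0)
    L <- adm[pick, , drop = FALSE]
    if (anyDuplicated(L[, 1]) || anyDuplicated(L[, 2])) next
    k <- nrow(L)
    cost <- sum(d2[L]) + alt * (n - k) + alt * (m - k) + eps * k
    if (cost < bestCost - 1e-12) {
      bestCost <- cost; best <- L
    }
  }
  best[order(best[, 1]), , drop = FALSE]
}

# exhaustive Otsu: maximise between-class variance over all 255 cuts of
# the 256-bin min-max histogram; returns the winning cut bin (0-based)
otsuBinOracle <- function(values) {
  lo <- min(values); hi <- max(values)
  bins <- pmin(floor((values - lo) / (hi - lo) * 256), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(h)
  bestVar <- -1; bestK <- NA
  for (k in 0:254) {
    w0 <- sum(h[1:(k + 1)]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(k + 1)] * (0:k)) / sum(h[1:(k + 1)])
    mu1 <- sum(h[(k + 2):256] * ((k + 1):255)) / sum(h[(k + 2):256])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > bestVar + 1e-12) {
      bestVar <- v; bestK <- k
    }
  }
  bestK
}

# dense-mask centroid, independent of the store implementations
maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE) - 1L
  colMeans(idx)
}

# a random linear workflow over lightweight no-op modules with a random
# dependency structure; returns the Workflow (module ids pre-registered by
# registerNoopModules)
registerNoopModules <- function() {
  if (!moduleExists("noop_producer"))
    registerModule("noop_producer", function(params, ws, seed) NULL, "test")
  if (!moduleExists("noop_transform"))
    registerModule("noop_transform", function(params, ws, seed) NULL, "test")
}

randomWorkflow <- function(nModules, seed) {
  registerNoopModules()
  set.seed(seed)
  mods <- list()
  produced <- character(0)
  for (i in seq_len(nModules)) {
    out <- sprintf("img%02d", i)
    if (length(produced) && runif(1) < 0.7) {
      nIn <- sample(1:min(2, length(produced)), 1)
      ins <- sample(produced, nIn)
      params <- c(lapply(seq_along(ins), function(k)
        wfParam(paste0("input_image", k), "input-image", ins[k])),
        list(wfParam("output_image", "output-image", out)))
      mods[[i]] <- do.call(moduleSpec, c(list("noop_transform"), params,
                                         list(nickname = sprintf("mod%02d", i))))
    } else {
      mods[[i]] <- moduleSpec("noop_producer",
                              wfParam("output_image", "output-image", out),
                              nickname = sprintf("mod%02d", i))
    }
    produced <- c(produced, out)
  }
  do.call(workflow, mods)
}
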