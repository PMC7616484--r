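#' Solve a square linear assignment problem
#'
#' Minimises the total cost of a perfect row-column matching by the
#' Jonker-Volgenant shortest-augmenting-path method with potentials
#' (O(n^3)). Blocked pairings are encoded as very large finite costs by the
#' caller. Deterministic: ties are resolved by the first (lowest-index)
#' column reached, so callers ordering rows/columns by object id get
#' reproducible assignments.
#'
#' @param cost square numeric cost matrix.
#' @return Integer vector a with a[i] = column assigned to row i.
#' @export
solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  if (n == 0L) return(integer(0))
  u <- numeric(n)
  v <- numeric(n + 1)          # column potentials; index 1 is virtual col 0
  p <- integer(n + 1)          # p[j+1] = row currently assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0] - v[j + 1]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j + 1] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}

.BLOCKED <- 1e12

# linear-assignment links between two frames of centroids, Jaqaman-style:
# the (n+m) x (n+m) matrix couples real links (squared distances), per-object
# non-link alternatives (altFactor x max admissible cost on the diagonal) and
# the transposed feasibility block.
.linkFrames <- function(ca, cb, maxDist, altFactor = 1.05) {
  n <- nrow(ca); m <- nrow(cb)
  if (n == 0L || m == 0L) return(cbind(integer(0), integer(0)))
  d2 <- outer(seq_len(n), seq_len(m), Vectorize(function(i, j)
    sum((ca[i, ] - cb[j, ])^2)))
  adm <- d2 <= maxDist^2
  if (!any(adm)) return(cbind(integer(0), integer(0)))
  alt <- altFactor * max(d2[adm])
  eps <- min(d2[adm])
  tl <- ifelse(adm, d2, .BLOCKED)
  tr <- matrix(.BLOCKED, n, n); diag(tr) <- alt
  bl <- matrix(.BLOCKED, m, m); diag(bl) <- alt
  br <- ifelse(t(adm), eps, .BLOCKED)
  cost <- rbind(cbind(tl, tr), cbind(bl, br))
  a <- solveAssignment(cost)
  links <- which(a[seq_len(n)] <= m)
  cbind(links, a[links])
}

#' Track objects across timepoints
#'
#' Frame-to-frame linking in the style of the Jaqaman linear-assignment
#' tracker: for each pair of consecutive frames an assignment problem over
#' squared calibrated centroid distances is solved, in which every object
#' also has a non-link alternative costed at \code{altFactor} times the
#' largest admissible linking cost (links beyond \code{maxDist} are
#' inadmissible). Chains of links become Track objects — coordinate-less
#' linking objects parenting their per-frame detections. Every input
#' object receives exactly one Track parent; objects that link to nothing
#' start (or remain) tracks of their own. Gap closing, splitting and
#' merging are out of scope.
#'
#' @param objects an \code{\link{ObjectSet}} spanning one or more frames.
#' @param maxDist maximum linking distance in calibrated units; must be
#'   positive.
#' @param trackName class name for the new track set.
#' @param altFactor alternative-cost factor (default 1.05).
#' @return The new Track \code{\link{ObjectSet}}; parent links are
#'   assigned as a side effect. An empty input yields an empty track set.
#' @export
trackObjects <- function(objects, maxDist, trackName = "Tracks",
                         altFactor = 1.05) {
  stopifnot(maxDist > 0)
  tracks <- ObjectSet$new(className = trackName,
                          calibration = objects$calibration)
  members <- objects$objects()
  if (!length(members)) return(tracks)
  cal <- objects$calibration
  tps <- vapply(members, function(o) o$timepoint, 0L)
  frames <- sort(unique(tps))
  centOf <- function(o) {
    cen <- objectCentroid(o, cal)
    c(cen["x_cal"], cen["y_cal"], cen["z_cal"])
  }
  trackOf <- new.env(parent = emptyenv())
  startTrack <- function(o) {
    tr <- tracks$newObj(timepoint = 0L, store = emptyStore())
    assignParent(o, tr)
    assign(as.character(o$id), tr, envir = trackOf)
  }
  byFrame <- function(t) {
    objs <- members[tps == t]
    objs[order(vapply(objs, function(o) o$id, 0L))]
  }
  for (o in byFrame(frames[1])) startTrack(o)
  for (fi in seq_along(frames)[-1]) {
    ta <- frames[fi - 1]; tb <- frames[fi]
    aObjs <- byFrame(ta); bObjs <- byFrame(tb)
    linked <- rep(FALSE, length(bObjs))
    if (tb == ta + 1L) {  # strictly consecutive frames only (no gap closing)
      ca <- do.call(rbind, lapply(aObjs, centOf))
      cb <- do.call(rbind, lapply(bObjs, centOf))
      links <- .linkFrames(ca, cb, maxDist, altFactor)
      for (r in seq_len(nrow(links))) {
        a <- aObjs[[links[r, 1]]]; b <- bObjs[[links[r, 2]]]
        tr <- get(as.character(a$id), envir = trackOf)
        assignParent(b, tr)
        assign(as.character(b$id), tr, envir = trackOf)
        linked[links[r, 2]] <- TRUE
      }
    }
    for (k in which(!linked)) startTrack(bObjs[[k]])
  }
  tracks
}

#' Measure track motion
#'
#' For each track, orders its child detections by timepoint and measures,
#' from their calibrated centroids: total path length (sum of step
#' lengths), Euclidean displacement (first to last), directionality ratio
#' (displacement / path length, in [0, 1]), mean velocity (path length /
#' elapsed time, using the frame interval) and duration in frames. Tracks
#' with a single detection get path length 0 and missing directionality
#' and velocity. Per-step instantaneous speeds are written onto the child
#' objects as \code{INST_SPEED}.
#'
#' @param tracks the Track \code{\link{ObjectSet}}.
#' @param childClass class name of the tracked detections.
#' @return \code{tracks}, invisibly (measurements added in place).
#' @export
measureTrackMotion <- function(tracks, childClass) {
  for (tr in tracks$objects()) {
    kids <- getChildren(tr, childClass)
    if (!length(kids)) next
    tp <- vapply(kids, function(o) o$timepoint, 0L)
    if (anyDuplicated(tp))
      stop(sprintf("track %d has children with duplicate timepoints", tr$id))
    kids <- kids[order(tp)]
    tp <- sort(tp)
    cal <- NULL
    cen <- t(vapply(kids, function(o) {
      ci <- objectCentroid(o, tracks$calibration)
      c(ci["x_cal"], ci["y_cal"], ci["z_cal"])
    }, numeric(3)))
    nSteps <- nrow(cen) - 1L
    dt <- frameInterval(tracks$calibration)
    if (nSteps >= 1L) {
      steps <- sqrt(rowSums((cen[-1, , drop = FALSE] -
                               cen[-nrow(cen), , drop = FALSE])^2))
      path <- sum(steps)
      disp <- sqrt(sum((cen[nrow(cen), ] - cen[1, ])^2))
      elapsed <- (tp[length(tp)] - tp[1]) * dt
      for (k in seq_len(nSteps)) {
        stepTime <- (tp[k + 1] - tp[k]) * dt
        kids[[k + 1]]$setMeasurement("INST_SPEED", steps[k] / stepTime)
      }
      tr$setMeasurement("TRACK_PATH_LENGTH_CAL", path)
      tr$setMeasurement("TRACK_DISPLACEMENT_CAL", disp)
      tr$setMeasurement("TRACK_DIRECTIONALITY",
                        if (path > 0) disp / path else NA_real_)
      tr$setMeasurement("TRACK_MEAN_VELOCITY", path / elapsed)
    } else {
      tr$setMeasurement("TRACK_PATH_LENGTH_CAL", 0)
      tr$setMeasurement("TRACK_DISPLACEMENT_CAL", 0)
      tr$setMeasurement("TRACK_DIRECTIONALITY", NA_real_)
      tr$setMeasurement("TRACK_MEAN_VELOCITY", NA_real_)
    }
    tr$setMeasurement("TRACK_DURATION_FRAMES", tp[length(tp)] - tp[1] + 1L)
  }
  invisible(tracks)
}
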