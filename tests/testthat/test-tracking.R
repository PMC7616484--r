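# build a detection set directly from centre coordinates:
# coords = data.frame(track (truth), frame, x, y)
detectionsFromTruth <- function(truth, cal = SpatialCalibration(
                                  frameInterval = 1)) {
  set <- ObjectSet$new(className = "Spots", calibration = cal)
  for (k in seq_len(nrow(truth))) {
    o <- set$newObj(timepoint = truth$frame[k])
    o$store <- storeAddVoxel(emptyStore(), truth$x[k], truth$y[k], 0)
  }
  set
}

truthPartition <- function(truth, set, tracks) {
  # map each truth track to the multiset of (frame, x, y) of its members
  got <- lapply(tracks$objects(), function(tr)
    sort(vapply(getChildren(tr, set$className), function(o) {
      v <- storeVoxels(o$store)
      sprintf("%d:%d:%d", o$timepoint, v[1, 1], v[1, 2])
    }, "")))
  want <- lapply(split(truth, truth$track), function(d)
    sort(sprintf("%d:%d:%d", d$frame, d$x, d$y)))
  setequal(lapply(got, paste, collapse = "|"),
           lapply(want, paste, collapse = "|"))
}

test_that("assignment solver matches exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n), n, n)
    a <- solveAssignment(cost)
    best <- Inf
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    for (p in perms(seq_len(n)))
      best <- min(best, sum(cost[cbind(seq_len(n), p)]))
    expect_equal(sum(cost[cbind(seq_len(n), a)]), best, tolerance = 1e-12)
  }
})

test_that("frame linking matches the exhaustive Jaqaman-objective oracle", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    ca <- matrix(runif(2 * n, 0, 30), n, 2)
    cb <- matrix(runif(2 * m, 0, 30), m, 2)
    got <- imflow:::.linkFrames(cbind(ca, 0), cbind(cb, 0), maxDist = 12)
    want <- linkOracle(ca, cb, maxDist = 12)
    if (is.null(want)) want <- cbind(integer(0), integer(0))
    got <- got[order(got[, 1]), , drop = FALSE]
    expect_equal(unname(got), unname(want), info = sprintf("rep %d", rep))
  }
})

test_that("parallel spots are tracked full length and match truth", {
  fix <- makeMovingSpots(nSpots = 2, nFrames = 5, step = c(3, 4),
                         noiseSigma = 0, seed = 2)
  set <- detectionsFromTruth(fix$truth)
  tracks <- trackObjects(set, maxDist = 10, trackName = "Tracks")
  expect_equal(tracks$size(), 2)
  expect_true(truthPartition(fix$truth, set, tracks))
  # conservation: every detection has exactly one Track parent
  for (o in set$objects())
    expect_false(is.null(getParent(o, "Tracks")))
  nChildren <- sum(vapply(tracks$objects(), function(tr)
    length(getChildren(tr, "Spots")), 0L))
  expect_equal(nChildren, set$size())
})

test_that("a disappearing spot ends its track without spurious links", {
  truth <- data.frame(track = c(1, 1, 2, 2, 2), frame = c(0, 1, 0, 1, 2),
                      x = c(0, 5, 40, 45, 50), y = 0)
  set <- detectionsFromTruth(truth)
  tracks <- trackObjects(set, maxDist = 10)
  expect_equal(tracks$size(), 2)
  lengths <- sort(vapply(tracks$objects(), function(tr)
    length(getChildren(tr, "Spots")), 0L))
  expect_equal(lengths, c(2L, 3L))
})

test_that("crossing spots link by global cost, not greed", {
  # a1 (0,0) -> near b2 (1,0); a2 (10,0) -> near b1 (9,0): the globally
  # optimal pairing is a1-b2, a2-b1
  ca <- rbind(c(0, 0, 0), c(10, 0, 0))
  cb <- rbind(c(9, 0, 0), c(1, 0, 0))
  links <- imflow:::.linkFrames(ca, cb, maxDist = 20)
  expect_equal(links[order(links[, 1]), 2], c(2L, 1L))
})

test_that("track motion measurements follow the 3-4-5 construction", {
  truth <- data.frame(track = 1, frame = 0:2, x = c(0, 3, 6), y = c(0, 4, 8))
  set <- detectionsFromTruth(truth)
  tracks <- trackObjects(set, maxDist = 10)
  measureTrackMotion(tracks, "Spots")
  tr <- tracks$getObj(1L)
  expect_equal(tr$getMeasurement("TRACK_PATH_LENGTH_CAL"), 10)
  expect_equal(tr$getMeasurement("TRACK_DISPLACEMENT_CAL"), 10)
  expect_equal(tr$getMeasurement("TRACK_DIRECTIONALITY"), 1.0)
  expect_equal(tr$getMeasurement("TRACK_MEAN_VELOCITY"), 5)
  expect_equal(tr$getMeasurement("TRACK_DURATION_FRAMES"), 3)
  # per-step instantaneous speeds land on the children
  kids <- getChildren(tr, "Spots")
  speeds <- vapply(kids, function(o) o$getMeasurement("INST_SPEED"), 0)
  expect_equal(unname(sort(speeds[!is.na(speeds)])), c(5, 5))

  # out-and-back: displacement 0, directionality 0
  t2 <- data.frame(track = 1, frame = 0:2, x = c(0, 5, 0), y = 0)
  s2 <- detectionsFromTruth(t2)
  tk2 <- trackObjects(s2, maxDist = 10)
  measureTrackMotion(tk2, "Spots")
  expect_equal(tk2$getObj(1L)$getMeasurement("TRACK_DISPLACEMENT_CAL"), 0)
  expect_equal(tk2$getObj(1L)$getMeasurement("TRACK_DIRECTIONALITY"), 0)

  # single detection: duration 1, path 0, directionality missing
  t3 <- data.frame(track = 1, frame = 0, x = 3, y = 3)
  tk3 <- trackObjects(detectionsFromTruth(t3), maxDist = 10)
  measureTrackMotion(tk3, "Spots")
  expect_equal(tk3$getObj(1L)$getMeasurement("TRACK_DURATION_FRAMES"), 1)
  expect_equal(tk3$getObj(1L)$getMeasurement("TRACK_PATH_LENGTH_CAL"), 0)
  expect_true(is.na(tk3$getObj(1L)$getMeasurement("TRACK_DIRECTIONALITY")))
})

test_that("directionality lies in [0, 1] on random trajectories", {
  set.seed(55)
  for (rep in 1:20) {
    nf <- sample(3:8, 1)
    truth <- data.frame(track = 1, frame = seq_len(nf) - 1L,
                        x = cumsum(sample(-3:3, nf, TRUE)),
                        y = cumsum(sample(-3:3, nf, TRUE)))
    truth$x <- truth$x - min(truth$x); truth$y <- truth$y - min(truth$y)
    set <- detectionsFromTruth(truth)
    tracks <- trackObjects(set, maxDist = 20)
    measureTrackMotion(tracks, "Spots")
    for (tr in tracks$objects()) {
      dirn <- tr$getMeasurement("TRACK_DIRECTIONALITY")
      if (!is.na(dirn)) {
        expect_gte(dirn, 0); expect_lte(dirn, 1)
      }
    }
  }
})

test_that("track assignments recover ground truth across seeds", {
  for (seed in 1:15) {
    set.seed(seed + 100)
    nSpots <- sample(2:5, 1); nFrames <- sample(5:10, 1)
    fix <- makeMovingSpots(nSpots = nSpots, nFrames = nFrames,
                           step = c(3, 4), noiseSigma = 0, seed = seed)
    set <- detectionsFromTruth(fix$truth)
    tracks <- trackObjects(set, maxDist = 10)
    expect_equal(tracks$size(), nSpots)
    expect_true(truthPartition(fix$truth, set, tracks))
  }
})

test_that("the full pipeline tracks rendered spot images", {
  fix <- makeMovingSpots(nSpots = 3, nFrames = 4, step = c(3, 4),
                         noiseSigma = 0, seed = 9)
  set <- identifyObjects(fix$image, "Spots")
  expect_equal(set$size(), 12)
  tracks <- trackObjects(set, maxDist = 10)
  expect_equal(tracks$size(), 3)
  measureTrackMotion(tracks, "Spots")
  for (tr in tracks$objects()) {
    # rigid translation of a rasterised disk moves its centroid exactly
    expect_equal(tr$getMeasurement("TRACK_PATH_LENGTH_CAL"), 15)
    expect_equal(tr$getMeasurement("TRACK_DIRECTIONALITY"), 1.0)
  }
})

test_that("empty input yields an empty track set", {
  set <- ObjectSet$new(className = "Spots")
  tracks <- trackObjects(set, maxDist = 5)
  expect_equal(tracks$size(), 0)
})
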