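# Expected node counts below were computed with the brute-force
# subdivision oracles in helper-oracles.R and frozen.

test_that("uniform and single-pixel masks subdivide as the oracle predicts", {
  # all-foreground 256x256: a single uniform root, no subdivision
  full <- matrix(TRUE, 256, 256)
  q <- storeFromMask(full, "quadtree")
  expect_equal(unname(storeNodeCounts(q)["total"]), 1)
  expect_equal(storeSize(q), 256 * 256)

  # single pixel at the origin of 256x256: oracle gives 33 nodes, 25 leaves
  single <- matrix(FALSE, 256, 256); single[1, 1] <- TRUE
  expect_equal(quadCountOracle(single), c(33L, 25L))
  qs <- storeFromMask(single, "quadtree")
  expect_equal(unname(storeNodeCounts(qs)), c(33, 25))

  # single voxel in 64^3: oracle gives 49 nodes (1 root + 6 levels x 8)
  vol <- array(FALSE, c(64, 64, 64)); vol[1, 1, 1] <- TRUE
  expect_equal(octCountOracle(vol)[1], 49L)
  os <- storeFromMask(vol, "octree")
  expect_equal(unname(storeNodeCounts(os)["total"]), 49)
})

test_that("single-pixel leaf-count law holds for k = 1..8", {
  for (k in 1:8) {
    n <- 2^k
    m <- matrix(FALSE, n, n); m[1, 1] <- TRUE
    oracle <- quadCountOracle(m)
    expect_equal(oracle, c(4L * k + 1L, 3L * k + 1L),
                 info = sprintf("oracle at k=%d", k))
    counts <- storeNodeCounts(storeFromMask(m, "quadtree"))
    expect_equal(unname(counts), c(4 * k + 1, 3 * k + 1),
                 info = sprintf("store at k=%d", k))
  }
})

test_that("the three store methods are equivalent on random masks", {
  for (seed in 1:12) {
    w <- sample(16:96, 1); h <- sample(16:96, 1); ns <- sample(1:4, 1)
    msk <- makeRandomMask(w, h, ns, nShapes = 4, seed = seed)
    stores <- lapply(c("pointlist", "quadtree", "octree"),
                     function(m) storeFromMask(msk, m))
    for (s in stores) {
      expect_identical(storeToMask(s, w, h, ns), msk)
      expect_equal(storeSize(s), sum(msk))
    }
    # identical canonical voxel lists
    expect_identical(storeVoxels(stores[[1]]), storeVoxels(stores[[2]]))
    expect_identical(storeVoxels(stores[[1]]), storeVoxels(stores[[3]]))
    # membership agrees on a probe sample
    probes <- cbind(sample(0:(w - 1), 20, TRUE), sample(0:(h - 1), 20, TRUE),
                    sample(0:(ns - 1), 20, TRUE))
    for (r in seq_len(nrow(probes))) {
      expected <- msk[probes[r, 1] + 1, probes[r, 2] + 1, probes[r, 3] + 1]
      for (s in stores)
        expect_equal(storeQuery(s, probes[r, 1], probes[r, 2], probes[r, 3]),
                     expected)
    }
  }
})

test_that("trees stay maximally merged, including after insertions", {
  for (seed in 1:5) {
    msk <- makeRandomMask(48, 48, 2, seed = seed)
    for (m in c("quadtree", "octree")) {
      s <- storeFromMask(msk, m)
      expect_true(isTRUE(storeIsMaximallyMerged(s)))
    }
  }
  # inserting the last pixel of a quadrant must re-merge ancestors
  s <- storeFromMask(matrix(FALSE, 4, 4), "quadtree")
  for (x in 0:3) for (y in 0:3) s <- storeAddVoxel(s, x, y, 0)
  expect_equal(unname(storeNodeCounts(s)["total"]), 1)
  expect_true(isTRUE(storeIsMaximallyMerged(s)))
  expect_equal(storeSize(s), 16)
})

test_that("duplicate insertion leaves pointlists unchanged", {
  s <- storeFromMask(matrix(c(1, 0, 0, 0), 2, 2), "pointlist")
  s2 <- storeAddVoxel(s, 0, 0, 0)
  expect_identical(storeVoxels(s), storeVoxels(s2))
  expect_equal(storeSize(s2), 1)
})

test_that("round trips and degenerate masks behave per contract", {
  # empty mask -> valid empty store, renders all-background
  for (m in c("pointlist", "quadtree", "octree")) {
    s <- storeFromMask(matrix(FALSE, 8, 8), m)
    expect_equal(storeSize(s), 0)
    expect_false(any(storeToMask(s, 8, 8, 1)))
  }
  # extents not covering a voxel -> bounds error
  s <- storeFromMask(matrix(c(0, 0, 0, 1), 2, 2), "pointlist")
  expect_error(storeToMask(s, 1, 1, 1), "extents")
  # unknown method -> configuration error
  expect_error(storeFromMask(matrix(1, 2, 2), "rle"))
})

test_that("membership and count match the pointlist contract exactly", {
  sq <- matrix(FALSE, 12, 12); sq[2:11, 2:11] <- TRUE
  for (m in c("pointlist", "quadtree", "octree")) {
    s <- storeFromMask(sq, m)
    expect_equal(storeSize(s), 100)
    expect_true(storeQuery(s, 5, 5, 0))
    expect_false(storeQuery(s, 0, 0, 0))
  }
})

test_that("abstract cost model reproduces the morphology cost orderings", {
  # single pixel in 256x256: pointlist 3 units beats quadtree 4 x 33 = 132
  single <- matrix(FALSE, 256, 256); single[128, 128] <- TRUE
  pl <- storeFromMask(single, "pointlist")
  qt <- storeFromMask(single, "quadtree")
  expect_equal(storeCost(pl), 3)
  expect_lt(storeCost(pl), storeCost(qt))

  # all-foreground 256x256: quadtree cost 4, pointlist 3 * 65536
  full <- matrix(TRUE, 256, 256)
  expect_equal(storeCost(storeFromMask(full, "quadtree")), 4)
  expect_equal(storeCost(storeFromMask(full, "pointlist")), 196608)

  # solid disk r = 100: the tree summarises the interior and wins
  disk <- .diskOracle <- matrix(FALSE, 256, 256)
  xs <- matrix(seq_len(256) - 1, 256, 256)
  ys <- matrix(rep(seq_len(256) - 1, each = 256), 256, 256)
  disk[(xs - 128)^2 + (ys - 128)^2 <= 100^2] <- TRUE
  expect_lt(storeCost(storeFromMask(disk, "quadtree")),
            storeCost(storeFromMask(disk, "pointlist")))

  # solid blobs of radius >= 16 already favour the quadtree
  blob <- matrix(FALSE, 256, 256)
  blob[(xs - 128)^2 + (ys - 128)^2 <= 16^2] <- TRUE
  expect_lt(storeCost(storeFromMask(blob, "quadtree")),
            storeCost(storeFromMask(blob, "pointlist")))

  # 1-px-wide skeleton keeps the pointlist ahead
  skel <- matrix(FALSE, 256, 256); skel[, 128] <- TRUE; skel[128, ] <- TRUE
  expect_lt(storeCost(storeFromMask(skel, "pointlist")),
            storeCost(storeFromMask(skel, "quadtree")))
})

test_that("downstream measurements are identical across store methods", {
  msk <- makeRandomMask(64, 64, 3, seed = 7)
  cents <- lapply(c("pointlist", "quadtree", "octree"), function(m) {
    o <- Obj$new(); o$store <- storeFromMask(msk, m)
    objectCentroid(o, SpatialCalibration(dx = 0.5, dy = 0.25, dz = 2))
  })
  expect_identical(cents[[1]], cents[[2]])
  expect_identical(cents[[1]], cents[[3]])
  expect_equal(unname(cents[[1]][c("x", "y", "z")]),
               unname(maskCentroid(msk)))
})
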