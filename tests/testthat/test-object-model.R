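makeSets <- function(...) {
  nms <- c(...)
  setNames(lapply(nms, function(n) ObjectSet$new(className = n)), nms)
}

test_that("parent assignment enforces the one-parent-per-class rule", {
  sets <- makeSets("Nuclei", "Tracks")
  n2 <- sets$Nuclei$newObj(); n2b <- sets$Nuclei$newObj()
  t1 <- sets$Tracks$newObj(); t3 <- sets$Tracks$newObj()

  assignParent(n2, t1)
  expect_identical(getParent(n2, "Tracks"), t1)
  expect_equal(vapply(getChildren(t1, "Nuclei"), function(o) o$id, 0L), n2$id)

  # reassignment unlinks the previous parent of that class
  assignParent(n2, t3)
  expect_identical(getParent(n2, "Tracks"), t3)
  expect_length(getChildren(t1, "Nuclei"), 0)

  # parents across different classes coexist
  sets2 <- makeSets("Cells", "Clusters", "Vesicles")
  v <- sets2$Vesicles$newObj()
  cell <- sets2$Cells$newObj(); clus <- sets2$Clusters$newObj()
  assignParent(v, cell); assignParent(v, clus)
  expect_identical(getParent(v, "Cells"), cell)
  expect_identical(getParent(v, "Clusters"), clus)
})

test_that("self-parenting and ancestry cycles are rejected", {
  sets <- makeSets("A", "B", "C")
  a <- sets$A$newObj(); b <- sets$B$newObj(); c <- sets$C$newObj()
  expect_error(assignParent(a, a), "own parent")
  assignParent(b, a)  # a is parent of b
  assignParent(c, b)  # a -> b -> c
  expect_error(assignParent(a, c), "cycle")
})

test_that("partner links are symmetric and idempotent", {
  sets <- makeSets("Edges", "Junctions")
  e <- sets$Edges$newObj()
  j1 <- sets$Junctions$newObj(); j2 <- sets$Junctions$newObj()
  assignPartners(e, j1)
  assignPartners(e, j2)
  assignPartners(e, j1)  # idempotent
  expect_equal(vapply(getPartners(e, "Junctions"), function(o) o$id, 0L),
               c(j1$id, j2$id))
  expect_equal(vapply(getPartners(j1, "Edges"), function(o) o$id, 0L), e$id)
  expect_error(assignPartners(e, e), "own partner")

  # a junction with three partnered edges lists all three, and vice versa
  e2 <- sets$Edges$newObj(); e3 <- sets$Edges$newObj()
  assignPartners(e2, j1); assignPartners(e3, j1)
  expect_length(getPartners(j1, "Edges"), 3)
  for (ed in getPartners(j1, "Edges"))
    expect_true(j1$id %in% vapply(getPartners(ed, "Junctions"),
                                  function(o) o$id, 0L))
})

test_that("hierarchy traversal reaches grandparents and child sets", {
  sets <- makeSets("Tracks", "Cells", "Vesicles", "Nuclei")
  tr <- sets$Tracks$newObj()
  cell <- sets$Cells$newObj()
  v <- sets$Vesicles$newObj()
  assignParent(cell, tr)
  assignParent(v, cell)

  # vesicle -> [Cells, Tracks] -> the track of the vesicle's cell
  res <- resolveHierarchy(v, c("Cells", "Tracks"))
  expect_length(res, 1)
  expect_identical(res[[1]], tr)

  # track -> [Nuclei]: one nucleus per frame, count = track length
  nuc <- lapply(0:3, function(t) {
    o <- sets$Nuclei$newObj(timepoint = t); assignParent(o, tr); o
  })
  expect_length(resolveHierarchy(tr, "Nuclei"), 4)

  # empty path = identity; unknown class = relationship error
  expect_identical(resolveHierarchy(v, character(0)), v)
  expect_error(resolveHierarchy(v, "Mitochondria"), "not a registered")
})

test_that("centroids agree with the dense-mask oracle and scale by calibration", {
  o <- Obj$new()
  o$store <- storeFromMask({
    m <- matrix(FALSE, 8, 8); m[4, 5] <- TRUE; m
  }, "pointlist")
  cal <- SpatialCalibration(dx = 0.5, dy = 0.5)
  cen <- objectCentroid(o, cal)
  expect_equal(unname(cen[c("x", "y", "z")]), c(3, 4, 0))
  expect_equal(unname(cen[c("x_cal", "y_cal")]), c(1.5, 2.0))

  # 2x2 square at the origin -> (0.5, 0.5, 0) by symmetry
  o$store <- storeFromMask({
    m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE; m
  }, "quadtree")
  expect_equal(unname(objectCentroid(o)[c("x", "y", "z")]), c(0.5, 0.5, 0))

  # random blob equals the independent dense centroid
  msk <- makeRandomMask(32, 32, 2, seed = 11)
  o$store <- storeFromMask(msk, "octree")
  expect_equal(unname(objectCentroid(o)[c("x", "y", "z")]),
               unname(maskCentroid(msk)))

  # empty store: missing values, not an error
  o$store <- emptyStore()
  expect_true(all(is.na(objectCentroid(o))))
})

test_that("random operation sequences never break the relationship audit", {
  set.seed(402)
  sets <- makeSets("A", "B", "C", "D")
  pool <- unlist(lapply(sets, function(s)
    lapply(1:6, function(i) s$newObj())), use.names = FALSE)
  for (op in 1:1000) {
    i <- sample(length(pool), 1); j <- sample(length(pool), 1)
    a <- pool[[i]]; b <- pool[[j]]
    kind <- sample(c("parent", "unparent", "partner", "unpartner"), 1)
    switch(kind,
      parent = try(assignParent(a, b), silent = TRUE),
      unparent = removeParent(a, b$className),
      partner = try(assignPartners(a, b), silent = TRUE),
      unpartner = removePartners(a, b))
  }
  expect_true(isTRUE(auditRelationships(sets)))
  # and parent graphs stayed acyclic
  for (o in pool) expect_false(imflow:::.isAncestor(o, o))
})
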