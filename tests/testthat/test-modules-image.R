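test_that("TIFF save/load round trips 5D data and calibration exactly", {
  cal <- SpatialCalibration(dx = 0.65, dy = 0.65, dz = 2,
                            spatialUnit = "micron", frameInterval = 0.5,
                            timeUnit = "s")
  arr <- array(sample(0:4095, 4 * 5 * 1 * 3 * 2, replace = TRUE),
               c(4, 5, 1, 3, 2))
  img <- newImageStack("Stack", arr, cal)
  path <- file.path(tempdir(), "roundtrip", "stack.tif")
  saveImage(img, path)  # auto-creates the subfolder
  back <- loadImage(path)
  expect_identical(back$data, img$data)
  expect_true(sameCalibration(back$calibration, cal))
  expect_equal(unname(back$dims()), c(4, 5, 1, 3, 2))

  # an RGB overlay round-trips as a 3-channel image
  rgb <- newImageStack("Overlay", array(sample(0:255, 6 * 6 * 3,
                                               replace = TRUE),
                                        c(6, 6, 3, 1, 1)))
  p2 <- file.path(tempdir(), "roundtrip", "rgb.tif")
  saveImage(rgb, p2)
  back2 <- loadImage(p2)
  expect_identical(back2$data, rgb$data)
  expect_equal(unname(back2$dims())[3], 3)
})

test_that("plain TIFFs load with singleton axes and default calibration", {
  m <- matrix(runif(64 * 64), 64, 64)
  p <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m, p)
  expect_warning(img <- loadImage(p), "calibration")
  expect_equal(unname(img$dims()), c(64, 64, 1, 1, 1))
  expect_equal(img$calibration@dx, 1)

  # 10-page stack -> z axis
  p2 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(replicate(10, matrix(runif(16), 4, 4), simplify = FALSE), p2)
  expect_warning(img2 <- loadImage(p2), "calibration")
  expect_equal(unname(img2$dims()), c(4, 4, 1, 10, 1))

  expect_error(loadImage("/no/such/file.tif"), "not found")
  bad <- tempfile(fileext = ".tif")
  writeLines("this is not a tiff", bad)
  expect_error(loadImage(bad), "TIFF")
})

test_that("Otsu matches exhaustive between-class-variance search", {
  # bimodal two-level image: threshold falls strictly between the modes
  vals <- c(rep(10, 500), rep(200, 500))
  thr <- otsuThreshold(vals)
  expect_gt(thr, 10); expect_lt(thr, 200)

  for (seed in 1:8) {
    set.seed(seed)
    vals <- c(rnorm(400, 40, 12), rnorm(300, 180, 20))
    thr <- otsuThreshold(vals)
    lo <- min(vals); hi <- max(vals)
    binOfThr <- (thr - lo) / (hi - lo) * 256 - 0.5
    expect_equal(round(binOfThr), otsuBinOracle(vals))
  }
  # against the independent EBImage implementation (on its [0,1] scale)
  set.seed(99)
  vals <- c(runif(600, 0, 0.3), runif(400, 0.6, 1))
  ref <- EBImage::otsu(EBImage::Image(matrix(vals, 40, 25)), range = c(0, 1))
  # both maximise the same criterion; ties inside an empty histogram gap
  # may be broken differently, so compare the induced classifications
  expect_identical(vals > otsuThreshold(vals), vals > ref)
})

test_that("thresholding follows the declared contract", {
  img <- newImageStack("Raw", matrix(c(100, 130, 100, 130), 2, 2))
  out <- applyThreshold(img, "manual", manualValue = 128,
                        outputName = "Binary")
  expect_equal(sum(out$data == 255), 2)
  expect_equal(sort(unique(as.vector(out$data))), c(0, 255))
  expect_equal(out$name, "Binary")

  # manual threshold outside the intensity range is rejected
  expect_error(applyThreshold(img, "manual", manualValue = 500), "range")

  # two-level image via otsu: only the upper mode is foreground
  img2 <- newImageStack("Raw", matrix(rep(c(10, 200), each = 32), 8, 8))
  out2 <- applyThreshold(img2, "otsu")
  expect_equal(sum(out2$data > 0), 32)

  # constant image: warning plus all-background output
  flat <- newImageStack("Flat", matrix(7, 4, 4))
  expect_warning(out3 <- applyThreshold(flat, "otsu"), "constant")
  expect_true(all(out3$data == 0))

  # idempotence: manual threshold between the two binary levels
  again <- applyThreshold(out, "manual", manualValue = 128)
  expect_identical(again$data, out$data)
})

test_that("fill holes closes enclosed background only", {
  ring <- matrix(0, 9, 9)
  ring[3:7, 3:7] <- 255; ring[4:6, 4:6] <- 0
  img <- newImageStack("Ring", ring)
  filled <- fillHoles(img)
  expect_equal(sum(filled$data > 0), 25)  # solid 5x5 square

  solid <- newImageStack("Solid", ring * 0 + {
    m <- matrix(0, 9, 9); m[3:7, 3:7] <- 255; m
  })
  expect_identical(fillHoles(solid)$data, solid$data)

  # background touching the border stays background
  open_ <- matrix(0, 9, 9); open_[3:7, 3:7] <- 255; open_[4:6, 1:6] <- 0
  expect_equal(sum(fillHoles(newImageStack("Open", open_))$data > 0),
               sum(open_ > 0))

  expect_error(fillHoles(newImageStack("Gray", matrix(1:9, 3, 3))), "binary")
})

test_that("outline overlay colours boundaries deterministically", {
  m <- matrix(0, 9, 9); m[4:6, 4:6] <- 255
  img <- newImageStack("Raw", m)
  objs <- identifyObjects(newImageStack("Bin", m), "Sq")
  ov <- addOutlineOverlay(img, objs, seed = 7)
  expect_equal(unname(ov$dims())[3], 3)
  # centre pixel keeps the grayscale on all channels; the 8 border pixels
  # of the 3x3 square are recoloured
  expect_equal(ov$data[5, 5, , 1, 1], rep(255, 3))
  border <- rbind(c(4, 4), c(5, 4), c(6, 4), c(4, 5), c(6, 5),
                  c(4, 6), c(5, 6), c(6, 6))
  recoloured <- apply(border, 1, function(p)
    length(unique(ov$data[p[1], p[2], , 1, 1])) > 1 ||
      any(ov$data[p[1], p[2], , 1, 1] != 255))
  expect_true(all(recoloured))
  # pixels off the object keep the grayscale
  expect_equal(ov$data[1, 1, , 1, 1], rep(0, 3))

  # same seed, same image; two objects get distinct colours
  ov2 <- addOutlineOverlay(img, objs, seed = 7)
  expect_identical(ov$data, ov2$data)
  m2 <- m; m2[1:2, 1:2] <- 255
  objs2 <- identifyObjects(newImageStack("Bin", m2), "Sq2")
  ov3 <- addOutlineOverlay(newImageStack("Raw2", m2), objs2, seed = 7)
  c1 <- ov3$data[1, 1, , 1, 1]; c2 <- ov3$data[4, 4, , 1, 1]
  expect_false(all(c1 == c2))

  # empty object set: plain RGB rendering of the input
  ovE <- addOutlineOverlay(img, ObjectSet$new(className = "None",
                                              calibration = img$calibration),
                           seed = 1)
  for (cc in 1:3) expect_equal(ovE$data[, , cc, 1, 1], m)
})

test_that("connected components labelling honours connectivity", {
  # two diagonal pixels: separate under 4-connectivity, joined under 8
  m <- array(0, c(4, 4, 1)); m[1, 1, 1] <- 1; m[2, 2, 1] <- 1
  expect_equal(max(labelComponents(m, inPlane = 4L)), 2)
  expect_equal(max(labelComponents(m, inPlane = 8L)), 1)

  # agreement with the independent EBImage labeller (2D, 4-connectivity)
  msk <- makeRandomMask(48, 48, 1, seed = 3)
  ours <- labelComponents(msk, inPlane = 4L)
  ref <- EBImage::bwlabel(msk[, , 1] + 0)
  expect_equal(max(ours), max(ref))

  # volumetric: stacked voxels joined only when volumetric connectivity on
  v <- array(0, c(3, 3, 2)); v[2, 2, 1] <- 1; v[2, 2, 2] <- 1
  expect_equal(max(labelComponents(v, volumetric = 6L)), 1)
  expect_equal(max(labelComponents(v, volumetric = 0L)), 2)
})
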