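test_that("minimum cross-entropy threshold equals the definitional minimizer", {
  # bimodal: half 10, half 200 -> threshold strictly between
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  thr <- minCrossEntropyThreshold(img)
  expect_gte(thr, 10)
  expect_lt(thr, 200)

  expect_error(minCrossEntropyThreshold(matrix(5, 4, 4)),
               "degenerate histogram")

  # oracle equivalence on random 8-bit images (direct objective, exhaustive)
  set.seed(101)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    expect_identical(minCrossEntropyThreshold(img), mceOracle(img))
  }
  # bimodal Gaussian-mixture images, closer to real projections
  for (i in 1:5) {
    img <- matrix(pmin(pmax(round(c(rnorm(300, 40, 12), rnorm(100, 180, 25))),
                            0), 255), 20, 20)
    expect_identical(minCrossEntropyThreshold(img), mceOracle(img))
  }
})

test_that("detectNuclei finds disjoint disks and filters sub-threshold noise", {
  centers <- rbind(c(20, 20), c(20, 60))
  img <- diskImage(80, 80, centers, r = 12)
  rois <- detectNuclei(Image2D(img), medianRadius = 1, minArea = 100)
  expect_identical(nLabels(rois), 2L)
  expect_true(all(provenance(rois) == "auto"))

  # label count is invariant to an additive intensity offset
  roisShift <- detectNuclei(Image2D(img + 37), medianRadius = 1,
                            minArea = 100)
  expect_identical(labelImage(roisShift), labelImage(rois))

  # pure noise: thresholding a unimodal histogram keeps ~half the pixels,
  # so the min-area filter must dominate every percolation cluster
  set.seed(5)
  noise <- matrix(runif(80 * 80, 0, 60), 80, 80)
  roisN <- detectNuclei(Image2D(noise), medianRadius = 1, minArea = 2000)
  expect_identical(nLabels(roisN), 0L)
})

test_that("touching nuclei are split with centroids near the true centers", {
  centers <- rbind(c(30, 26), c(30, 46))  # closer than the radius sum (2*12)
  img <- diskImage(60, 72, centers, r = 12)
  rois <- detectNuclei(Image2D(img), medianRadius = 1, minArea = 150,
                       splitTouching = TRUE)
  expect_identical(nLabels(rois), 2L)
  cent <- chromoseg:::labelCentroids(labelImage(rois))
  ds <- apply(centers, 1, function(ctr)
    min(sqrt((cent[, 1] - ctr[1])^2 + (cent[, 2] - ctr[2])^2)))
  expect_true(all(ds <= 3))

  # without splitting the pair stays merged
  roisNo <- detectNuclei(Image2D(img), medianRadius = 1, minArea = 150,
                         splitTouching = FALSE)
  expect_identical(nLabels(roisNo), 1L)
})

test_that("curation removes, adds and renumbers; inverse edits restore", {
  img <- diskImage(60, 90, rbind(c(15, 15), c(15, 60), c(45, 40)), r = 9)
  rois <- detectNuclei(Image2D(img), medianRadius = 0, minArea = 50)
  expect_identical(nLabels(rois), 3L)

  # empty edit is the identity
  same <- applyCuration(rois, list())
  expect_identical(labelImage(same), labelImage(rois))

  cur <- applyCuration(rois, list(removals = 2L))
  expect_identical(nLabels(cur), 2L)
  expect_identical(sort(unique(as.vector(labelImage(cur)))), c(0L, 1L, 2L))

  expect_error(applyCuration(rois, list(removals = 9L)), "absent")

  # add a square on background; area equals the point-in-polygon oracle
  poly <- rbind(c(50.5, 60.5), c(50.5, 75.5), c(58.5, 75.5), c(58.5, 60.5))
  cur2 <- applyCuration(rois, list(additions = list(poly)))
  expect_identical(nLabels(cur2), 4L)
  expect_identical(provenance(cur2)[4], "added")
  gotArea <- sum(labelImage(cur2) == 4L)
  pts <- expand.grid(y = 1:60, x = 1:90)
  oracle <- sum(mgcv::in.out(rbind(poly, poly[1, ]),
                             as.matrix(pts[, c("y", "x")])))
  expect_identical(gotArea, oracle)

  # polygon over an existing nucleus is refused
  bad <- rbind(c(10, 10), c(10, 22), c(22, 22), c(22, 10))
  expect_error(applyCuration(rois, list(additions = list(bad))), "overlaps")

  # add then remove returns to the original labels (up to renumbering)
  back <- applyCuration(cur2, list(removals = 4L))
  expect_identical(labelImage(back), labelImage(rois))

  # JSON edit roundtrip
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(removals = 2L,
                                   additions = list(poly)),
                              auto_unbox = FALSE), f)
  edit <- readCurationEdit(f)
  expect_identical(edit$removals, 2L)
  expect_equal(edit$additions[[1]][, 1], poly[, 1], ignore_attr = TRUE)
})

test_that("cropNucleus honors margins and clips at borders", {
  vox <- array(runif(3 * 50 * 50), c(3, 50, 50))
  st <- ZStack(vox)
  lab <- matrix(0L, 50, 50)
  lab[21:30, 21:30] <- 1L   # 10 x 10 square
  lab[1:8, 44:50] <- 2L     # touches two borders
  rois <- new("RoiSet", labelImage = lab, provenance = c("auto", "auto"),
              minArea = 10)

  cr0 <- cropNucleus(st, rois, 1L, marginFrac = 0)
  expect_identical(dim(voxels(cr0$stack)), c(3L, 10L, 10L))
  expect_true(all(cr0$mask))

  cr1 <- cropNucleus(st, rois, 1L, marginFrac = 0.1)
  expect_identical(dim(voxels(cr1$stack)), c(3L, 12L, 12L))

  cr2 <- cropNucleus(st, rois, 2L, marginFrac = 0.5)
  d2 <- dim(voxels(cr2$stack))
  expect_lte(d2[2], 50L); expect_lte(d2[3], 50L)
  expect_identical(cr2$box[["y0"]], 1L)
  expect_identical(cr2$box[["x1"]], 50L)

  expect_error(cropNucleus(st, rois, 7L), "absent")
})
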