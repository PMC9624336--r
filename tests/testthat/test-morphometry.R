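test_that("tri-level composition encodes the three classes and rejects leaks", {
  nuc <- diskMask(30, 30, 15, 15, 10)
  cc <- matrix(0L, 30, 30); cc[diskMask(30, 30, 13, 13, 2)] <- 1L

  tl <- composeTrilevel(nuc, cc)
  expect_setequal(unique(as.vector(pixels(tl))), c(0, 128, 255))
  expect_identical(sum(pixels(tl) == 255), sum(cc > 0))
  # every chromocenter pixel sits inside the nucleus region
  expect_true(all(nuc[pixels(tl) == 255]))

  empty <- composeTrilevel(nuc, matrix(0L, 30, 30))
  expect_setequal(unique(as.vector(pixels(empty))), c(0, 128))

  leak <- cc; leak[1, 1] <- 9L
  expect_error(composeTrilevel(nuc, leak), "outside")

  # decomposition inverts composition
  labs <- trilevelToLabels(tl)
  expect_identical(labs$nucleusLabels > 0L, nuc)
  expect_identical(labs$ccLabels > 0L, cc > 0L)
})

test_that("morphometrics reproduce the defining formulas on a hand example", {
  # nucleus of 100 px with mean intensity 10; one CC of 10 px with mean 30
  nuc <- matrix(FALSE, 20, 20); nuc[6:15, 6:15] <- TRUE
  cc <- matrix(0L, 20, 20); cc[8, 6:15] <- 1L
  img <- matrix(0, 20, 20)
  img[nuc] <- (100 * 10 - 10 * 30) / 90   # non-CC nucleus pixels
  img[cc == 1L] <- 30
  m <- measureNucleus(nuc, cc, img)
  expect_equal(m$hf, 0.1, tolerance = 1e-12)
  expect_equal(m$rhi, 3.0, tolerance = 1e-12)
  expect_equal(m$rhf, 0.3, tolerance = 1e-12)
  expect_identical(m$ccCount, 1L)
  expect_identical(m$units, "px2")
  expect_equal(m$nucleusArea, 100)

  # physical units
  m2 <- measureNucleus(nuc, cc, img, pixelSize = c(0.1, 0.1))
  expect_identical(m2$units, "um2")
  expect_equal(m2$nucleusArea, 1)
  expect_equal(m2$rhf, m$rhf)

  # no chromocenters -> zeros by convention, flagged by ccCount
  m0 <- measureNucleus(nuc, matrix(0L, 20, 20), img)
  expect_identical(m0$ccCount, 0L)
  expect_identical(c(m0$hf, m0$rhi, m0$rhf), c(0, 0, 0))

  expect_error(measureNucleus(matrix(FALSE, 20, 20), cc, img), "empty")
})

test_that("rhf identities and scale invariance hold on random nuclei", {
  set.seed(202)
  for (i in 1:100) {
    fx <- randomNucleusFixture()
    m <- measureNucleus(fx$nucleus, fx$cc, fx$intensity)
    expect_lt(abs(sum(m$raf) - m$hf), 1e-9)
    expect_lt(abs(m$rhf - m$hf * m$rhi), 1e-9)
    # algebraic identity: HF x RHI = total CC intensity / total nucleus
    if (m$ccCount > 0) {
      direct <- sum(fx$intensity[fx$cc > 0L]) / sum(fx$intensity[fx$nucleus])
      expect_lt(abs(m$rhf - direct), 1e-9)
    }
    expect_identical(m$ccCount, length(m$raf))
    expect_gte(m$hf, 0); expect_lte(m$hf, 1)
    # intensity rescaling leaves the dimensionless quantities unchanged
    k <- runif(1, 0.2, 8)
    mk <- measureNucleus(fx$nucleus, fx$cc, fx$intensity * k)
    expect_equal(c(mk$hf, mk$rhi, mk$rhf), c(m$hf, m$rhi, m$rhf),
                 tolerance = 1e-9)
  }
})

test_that("batch measurement equals per-nucleus calls and is deterministic", {
  # no touching pairs: the tri-level mask cannot represent separate labels
  # for touching nuclei, so the round-trip comparison needs disjoint ones
  sc <- generateScene(sceneConfig("light", seed = 12, touchingProb = 0))
  proj <- zProject(sc$noiseless, "max")
  tr <- sc$truth
  batch <- measureBatch(tr@nucleusLabels, tr@ccLabels, proj)
  n <- max(tr@nucleusLabels)
  expect_identical(nrow(batch$records), n)
  for (k in seq_len(n)) {
    m <- measureNucleus(tr@nucleusLabels == k, tr@ccLabels, proj)
    expect_equal(batch$records$hf[k], m$hf)
    expect_equal(batch$records$rhf[k], m$rhf)
    expect_identical(batch$records$cc_count[k], m$ccCount)
  }
  # reruns produce byte-identical CSV output
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeMorphometrics(batch, f1)
  writeMorphometrics(measureBatch(tr@nucleusLabels, tr@ccLabels, proj), f2)
  expect_identical(readLines(f1), readLines(f2))
  raf1 <- sub("(\\.[^.]+)$", "_raf\\1", f1)
  expect_true(file.exists(raf1))
  expect_identical(sum(read.csv(raf1)$nucleus_id > 0), nrow(batch$raf))

  # measuring from the tri-level mask agrees with the label images
  fromTl <- measureBatch(tr@trilevel, intensity = proj)
  expect_equal(sort(fromTl$records$rhf), sort(batch$records$rhf),
               tolerance = 1e-12)
})

test_that("ground-truth records match re-measurement on the noiseless scene", {
  for (s in c(31, 32)) {
    sc <- generateScene(sceneConfig("light", seed = s, noise = c(0, 0)))
    tr <- sc$truth
    # with noise disabled the rendered stack equals the noiseless one
    expect_identical(voxels(sc$stack), voxels(sc$noiseless))
    meas <- measureBatch(tr@nucleusLabels, tr@ccLabels,
                         zProject(sc$stack, "max"),
                         pixelSize = voxelSize(sc$stack)[2:3])
    expect_equal(meas$records$hf, tr@records$hf, tolerance = 1e-6)
    expect_equal(meas$records$rhi, tr@records$rhi, tolerance = 1e-6)
    expect_equal(meas$records$rhf, tr@records$rhf, tolerance = 1e-6)
  }
})
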