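test_that("network construction obeys the shape/range contract and seeding", {
  cfg <- uNetConfig(depth = 2L, baseFilters = 8L, inputSize = c(64L, 64L),
                    seed = 3L)
  m <- buildUNet(cfg)
  x <- matrix(runif(64 * 64), 64, 64)
  pr <- chromoseg:::unetForward(m, x)$probs
  expect_identical(dim(pr), c(64L, 64L))
  expect_true(all(pr >= 0 & pr <= 1))

  # identical config + seed -> identical initial parameters
  m2 <- buildUNet(cfg)
  expect_identical(m@params, m2@params)
  m3 <- buildUNet(uNetConfig(depth = 2L, baseFilters = 8L,
                             inputSize = c(64L, 64L), seed = 4L))
  expect_false(identical(m@params, m3@params))

  # input size not divisible by 2^depth is rejected
  expect_error(uNetConfig(depth = 5L, inputSize = c(48L, 48L)), "divisible")
  expect_error(uNetConfig(depth = 2L, loss = "mse"), "loss")
})

test_that("analytic gradients agree with central differences", {
  cfg <- uNetConfig(depth = 2L, baseFilters = 2L, inputSize = c(8L, 8L),
                    loss = "bcedice", seed = 42L)
  m <- buildUNet(cfg)
  set.seed(9)
  x <- matrix(runif(64), 8, 8)
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  fw <- chromoseg:::unetForward(m, x, keep = TRUE)
  ls <- chromoseg:::unetLoss(fw$probs, y, "bcedice")
  g <- chromoseg:::unetBackward(m, fw$cache, ls$dZ)
  lossAt <- function(p) {
    mm <- new("UNetModel", config = cfg, params = p)
    chromoseg:::unetLoss(chromoseg:::unetForward(mm, x)$probs, y,
                         "bcedice")$value
  }
  eps <- 1e-6
  cases <- list(
    list(get = function(gg) gg$enc[[1]]$W1[7],
         bump = function(p, e) { p$enc[[1]]$W1[7] <- p$enc[[1]]$W1[7] + e; p }),
    list(get = function(gg) gg$enc[[2]]$W2[25],
         bump = function(p, e) { p$enc[[2]]$W2[25] <- p$enc[[2]]$W2[25] + e; p }),
    list(get = function(gg) gg$bott$W1[11],
         bump = function(p, e) { p$bott$W1[11] <- p$bott$W1[11] + e; p }),
    list(get = function(gg) gg$dec[[1]]$W2[12],
         bump = function(p, e) { p$dec[[1]]$W2[12] <- p$dec[[1]]$W2[12] + e; p }),
    list(get = function(gg) gg$out$W[2],
         bump = function(p, e) { p$out$W[2] <- p$out$W[2] + e; p }))
  for (cs in cases) {
    num <- (lossAt(cs$bump(m@params, eps)) -
            lossAt(cs$bump(m@params, -eps))) / (2 * eps)
    expect_lt(abs(cs$get(g) - num) / max(1e-8, abs(num)), 1e-4)
  }
})

test_that("training reduces the loss and degenerate targets collapse to zero", {
  cfg <- uNetConfig(depth = 1L, baseFilters = 4L, inputSize = c(16L, 16L),
                    epochs = 10L, batchSize = 4L, learningRate = 5e-3,
                    seed = 2L)
  set.seed(8)
  imgs <- lapply(1:12, function(i) {
    m <- matrix(runif(256, 0, 0.3), 16, 16)
    m[diskMask(16, 16, runif(1, 6, 10), runif(1, 6, 10), 4)] <- 1
    m
  })
  msks <- lapply(imgs, function(m) (m > 0.6) + 0)
  tr <- trainUNet(buildUNet(cfg), imgs, msks)
  expect_lt(tail(tr$history, 1), tr$history[1])

  # fixed seed reproduces the training history exactly
  tr2 <- trainUNet(buildUNet(cfg), imgs, msks)
  expect_identical(tr$history, tr2$history)
  expect_identical(tr$model@params, tr2$model@params)

  # all-zero masks drive the predictions toward zero
  zero <- lapply(imgs, function(m) m * 0)
  trz <- trainUNet(buildUNet(cfg), imgs, zero)
  pr <- probs(predictHeatmap(trz$model, imgs[[1]]))
  expect_lt(mean(pr), 0.1)

  expect_error(trainUNet(buildUNet(cfg), list(), list()), "empty")
})

test_that("heatmaps stay in [0,1] and binarization is threshold-monotone", {
  set.seed(66)
  hm <- new("HeatmapPrediction", probs = matrix(runif(400), 20, 20))
  expect_identical(hm@threshold, 0.5)
  lo <- binarizeHeatmap(hm, 0.25)
  hi <- binarizeHeatmap(hm, 0.5)
  expect_true(all(lo[hi]))           # mask(0.5) subset of mask(0.25)
  expect_error(new("HeatmapPrediction", probs = matrix(2, 2, 2)), "0, 1")
})

test_that("models survive a save/load roundtrip", {
  cfg <- uNetConfig(depth = 1L, baseFilters = 2L, inputSize = c(8L, 8L),
                    seed = 5L)
  m <- buildUNet(cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  saveUNet(m, f)
  m2 <- loadUNet(f)
  expect_identical(m@params, m2@params)
  x <- matrix(runif(64), 8, 8)
  expect_identical(probs(predictHeatmap(m, x)), probs(predictHeatmap(m2, x)))
})

test_that("augmentation preserves geometry contracts", {
  set.seed(30)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- diskMask(32, 32, 14, 18, 6) + 0

  # multiplicity 1, or ops disabled: original pair only
  a1 <- augmentPair(img, msk, multiplicity = 1, seed = 1)
  expect_length(a1, 1)
  expect_identical(a1[[1]]$image, img)
  aOff <- augmentPair(img, msk, multiplicity = 3, seed = 1, ops = character(0))
  expect_identical(aOff[[2]]$image, img)

  aug <- augmentPair(img, msk, multiplicity = 8, seed = 7)
  for (p in aug) {
    expect_identical(dim(p$image), dim(img))
    # masks stay binary under every transform
    expect_true(all(p$mask %in% c(0, 1)))
  }
  # flips and 90-degree rotations preserve the foreground area exactly
  flipOnly <- augmentPair(img, msk, multiplicity = 6, seed = 2,
                          ops = c("flip", "rot90"))
  for (p in flipOnly) expect_identical(sum(p$mask), sum(msk))
  # seeded: same call twice gives identical output
  expect_identical(augmentPair(img, msk, 5, seed = 3),
                   augmentPair(img, msk, 5, seed = 3))
})
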