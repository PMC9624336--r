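#' UNetModel: a compact U-Net for binary segmentation
#'
#' An encoder-decoder with skip connections implemented directly in R: each
#' level applies two 3x3 convolutions with ReLU, levels are joined by 2x2
#' max pooling on the way down and nearest-neighbor upsampling plus channel
#' concatenation on the way up, and a final 1x1 convolution with sigmoid
#' yields a per-pixel object probability. Convolutions are evaluated as
#' sums of shifted BLAS matrix products, which keeps desk-scale
#' configurations (depth 2, 8 base filters, 64x64 tiles) fast on one CPU.
#'
#' @slot config the [UNetConfig-class] the model was built from.
#' @slot params list of parameter arrays (weights and biases per layer).
#' @seealso [buildUNet()], [trainUNet()], [predictHeatmap()]
#' @export
setClass("UNetModel",
  representation(config = "UNetConfig", params = "list"))

setMethod("show", "UNetModel", function(object) {
  np <- sum(rapply(object@params, length, how = "unlist"))
  cat(sprintf("UNetModel: depth %d, %d base filters, input %d x %d, %d parameters\n",
              object@config@depth, object@config@baseFilters,
              object@config@inputSize[1], object@config@inputSize[2],
              as.integer(np)))
})

#' Construct a UNetConfig
#'
#' @param depth pooling levels (input size must divide by 2^depth).
#' @param baseFilters filters at the first level.
#' @param inputSize integer(2) tile size (H, W).
#' @param loss "bce", "dice" or "bcedice".
#' @param epochs,batchSize,learningRate,seed training settings.
#' @return A [UNetConfig-class].
#' @export
uNetConfig <- function(depth = 2L, baseFilters = 8L, inputSize = c(64L, 64L),
                       loss = "bcedice", epochs = 10L, batchSize = 4L,
                       learningRate = 2e-3, seed = 1L) {
  new("UNetConfig", depth = as.integer(depth),
      baseFilters = as.integer(baseFilters),
      inputSize = as.integer(inputSize), loss = loss,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = learningRate, seed = as.integer(seed))
}

## ---- primitive layers (column-major (y, x) flattening throughout) ----

## 3x3 same convolution: X (H, W, Cin) -> (H, W, F)
conv3Fwd <- function(X, W, b) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; Cin <- d[3]; Fn <- dim(W)[4]
  Xa <- rbind(matrix(X, H * Wd, Cin), 0)
  M <- matrix(seq_len(H * Wd), H, Wd)
  pad <- matrix(H * Wd + 1L, H + 2L, Wd + 2L)
  pad[2:(H + 1L), 2:(Wd + 1L)] <- M
  Y <- matrix(rep(b, each = H * Wd), H * Wd, Fn)
  for (ky in 1:3) for (kx in 1:3) {
    idx <- as.vector(pad[(1:H) + ky - 1L, (1:Wd) + kx - 1L])
    Y <- Y + Xa[idx, , drop = FALSE] %*% matrix(W[ky, kx, , ], Cin, Fn)
  }
  array(Y, c(H, Wd, Fn))
}

## backward of conv3: returns list(dX, dW, db); relu applied outside
conv3Bwd <- function(dY, X, W) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; Cin <- d[3]; Fn <- dim(W)[4]
  dYm <- matrix(dY, H * Wd, Fn)
  Xa <- rbind(matrix(X, H * Wd, Cin), 0)
  M <- matrix(seq_len(H * Wd), H, Wd)
  pad <- matrix(H * Wd + 1L, H + 2L, Wd + 2L)
  pad[2:(H + 1L), 2:(Wd + 1L)] <- M
  dW <- array(0, dim(W))
  dXa <- matrix(0, H * Wd + 1L, Cin)
  for (ky in 1:3) for (kx in 1:3) {
    idx <- as.vector(pad[(1:H) + ky - 1L, (1:Wd) + kx - 1L])
    Sk <- Xa[idx, , drop = FALSE]
    dW[ky, kx, , ] <- crossprod(Sk, dYm)
    dSk <- dYm %*% t(matrix(W[ky, kx, , ], Cin, Fn))
    dXa[idx, ] <- dXa[idx, ] + dSk
  }
  list(dX = array(dXa[seq_len(H * Wd), , drop = FALSE], d),
       dW = dW, db = colSums(dYm))
}

## 2x2 max pooling; returns out plus argmax masks for backward
pool2Fwd <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  a11 <- X[i1, j1, , drop = FALSE]; a21 <- X[i2, j1, , drop = FALSE]
  a12 <- X[i1, j2, , drop = FALSE]; a22 <- X[i2, j2, , drop = FALSE]
  out <- pmax(a11, a21, a12, a22)
  m11 <- a11 == out
  m21 <- a21 == out & !m11
  m12 <- a12 == out & !m11 & !m21
  m22 <- !m11 & !m21 & !m12
  list(out = out, masks = list(m11, m21, m12, m22))
}

pool2Bwd <- function(dOut, masks, dimX) {
  H <- dimX[1]; W <- dimX[2]
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  dX <- array(0, dimX)
  dX[i1, j1, ] <- dOut * masks[[1]]
  dX[i2, j1, ] <- dOut * masks[[2]]
  dX[i1, j2, ] <- dOut * masks[[3]]
  dX[i2, j2, ] <- dOut * masks[[4]]
  dX
}

## nearest-neighbor 2x upsampling
up2Fwd <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

up2Bwd <- function(dOut) {
  d <- dim(dOut)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dOut[i1, j1, , drop = FALSE] + dOut[i1 + 1L, j1, , drop = FALSE] +
    dOut[i1, j1 + 1L, , drop = FALSE] + dOut[i1 + 1L, j1 + 1L, , drop = FALSE]
}

heInit <- function(ky, kx, cin, f) {
  array(rnorm(ky * kx * cin * f, sd = sqrt(2 / (ky * kx * cin))),
        c(ky, kx, cin, f))
}

#' Build a (seeded) U-Net
#'
#' Parameter initialization is He-scaled Gaussian, drawn under the config
#' seed, so the same config always yields identical initial parameters.
#'
#' @param config a [UNetConfig-class].
#' @return An untrained [UNetModel-class].
#' @export
buildUNet <- function(config = uNetConfig()) {
  validObject(config)
  set.seed(config@seed)
  D <- config@depth; F0 <- config@baseFilters
  filt <- F0 * 2L^(0:D)
  enc <- vector("list", D)
  cin <- 1L
  for (i in seq_len(D)) {
    enc[[i]] <- list(W1 = heInit(3, 3, cin, filt[i]), b1 = numeric(filt[i]),
                     W2 = heInit(3, 3, filt[i], filt[i]), b2 = numeric(filt[i]))
    cin <- filt[i]
  }
  bott <- list(W1 = heInit(3, 3, cin, filt[D + 1]), b1 = numeric(filt[D + 1]),
               W2 = heInit(3, 3, filt[D + 1], filt[D + 1]),
               b2 = numeric(filt[D + 1]))
  dec <- vector("list", D)
  up <- filt[D + 1]
  for (i in rev(seq_len(D))) {
    cinDec <- up + filt[i]  # upsampled + skip concat
    dec[[i]] <- list(W1 = heInit(3, 3, cinDec, filt[i]), b1 = numeric(filt[i]),
                     W2 = heInit(3, 3, filt[i], filt[i]), b2 = numeric(filt[i]))
    up <- filt[i]
  }
  outW <- matrix(rnorm(filt[1], sd = sqrt(2 / filt[1])), filt[1], 1)
  new("UNetModel", config = config,
      params = list(enc = enc, bott = bott, dec = dec,
                    out = list(W = outW, b = 0)))
}

## forward pass; returns probs (H, W) and, if keep, all caches for backward
unetForward <- function(model, x, keep = FALSE) {
  p <- model@params; D <- model@config@depth
  a <- array(x, c(dim(x), 1L))
  cache <- list(input = a, enc = vector("list", D), pool = vector("list", D),
                dec = vector("list", D))
  skips <- vector("list", D)
  for (i in seq_len(D)) {
    h1 <- pmax(conv3Fwd(a, p$enc[[i]]$W1, p$enc[[i]]$b1), 0)
    h2 <- pmax(conv3Fwd(h1, p$enc[[i]]$W2, p$enc[[i]]$b2), 0)
    skips[[i]] <- h2
    pl <- pool2Fwd(h2)
    if (keep) cache$enc[[i]] <- list(x = a, h1 = h1, h2 = h2, masks = pl$masks)
    a <- pl$out
  }
  b1 <- pmax(conv3Fwd(a, p$bott$W1, p$bott$b1), 0)
  b2 <- pmax(conv3Fwd(b1, p$bott$W2, p$bott$b2), 0)
  if (keep) cache$bott <- list(x = a, h1 = b1, h2 = b2)
  a <- b2
  for (i in rev(seq_len(D))) {
    upa <- up2Fwd(a)
    cat_ <- array(c(upa, skips[[i]]),
                  c(dim(upa)[1], dim(upa)[2], dim(upa)[3] + dim(skips[[i]])[3]))
    h1 <- pmax(conv3Fwd(cat_, p$dec[[i]]$W1, p$dec[[i]]$b1), 0)
    h2 <- pmax(conv3Fwd(h1, p$dec[[i]]$W2, p$dec[[i]]$b2), 0)
    if (keep) cache$dec[[i]] <- list(x = cat_, h1 = h1, h2 = h2,
                                     nUp = dim(upa)[3], dimA = dim(a))
    a <- h2
  }
  d <- dim(a)
  z <- matrix(a, d[1] * d[2], d[3]) %*% p$out$W + p$out$b
  probs <- matrix(1 / (1 + exp(-z)), d[1], d[2])
  if (keep) cache$final <- list(a = a, probs = probs)
  list(probs = probs, cache = if (keep) cache else NULL)
}

## backward pass from dL/dz (logit gradient, H x W matrix);
## returns gradient list with the same shape as params
unetBackward <- function(model, cache, dZ) {
  p <- model@params; D <- model@config@depth
  g <- list(enc = vector("list", D), bott = NULL, dec = vector("list", D),
            out = NULL)
  a <- cache$final$a
  d <- dim(a)
  dZm <- matrix(dZ, d[1] * d[2], 1)
  am <- matrix(a, d[1] * d[2], d[3])
  g$out <- list(W = crossprod(am, dZm), b = sum(dZm))
  dA <- array(dZm %*% t(p$out$W), d)
  skipGrads <- vector("list", D)
  for (i in seq_len(D)) {  # decoder, shallowest first (reverse of forward)
    cc <- cache$dec[[i]]
    dH2 <- dA * (cc$h2 > 0)
    b2 <- conv3Bwd(dH2, cc$h1, p$dec[[i]]$W2)
    dH1 <- b2$dX * (cc$h1 > 0)
    b1 <- conv3Bwd(dH1, cc$x, p$dec[[i]]$W1)
    g$dec[[i]] <- list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db)
    nUp <- cc$nUp
    dUp <- b1$dX[, , seq_len(nUp), drop = FALSE]
    skipGrads[[i]] <- b1$dX[, , nUp + seq_len(dim(b1$dX)[3] - nUp),
                            drop = FALSE]
    dA <- up2Bwd(dUp)  # gradient flowing into the next deeper stage
  }
  ## bottleneck
  dB2 <- dA * (cache$bott$h2 > 0)
  bb2 <- conv3Bwd(dB2, cache$bott$h1, p$bott$W2)
  dB1 <- bb2$dX * (cache$bott$h1 > 0)
  bb1 <- conv3Bwd(dB1, cache$bott$x, p$bott$W1)
  g$bott <- list(W1 = bb1$dW, b1 = bb1$db, W2 = bb2$dW, b2 = bb2$db)
  dPooled <- bb1$dX
  for (i in rev(seq_len(D))) {  # encoder, deepest first
    cc <- cache$enc[[i]]
    dH2 <- pool2Bwd(dPooled, cc$masks, dim(cc$h2)) + skipGrads[[i]]
    dH2 <- dH2 * (cc$h2 > 0)
    e2 <- conv3Bwd(dH2, cc$h1, p$enc[[i]]$W2)
    dH1 <- e2$dX * (cc$h1 > 0)
    e1 <- conv3Bwd(dH1, cc$x, p$enc[[i]]$W1)
    g$enc[[i]] <- list(W1 = e1$dW, b1 = e1$db, W2 = e2$dW, b2 = e2$db)
    dPooled <- if (i > 1L) e1$dX else NULL
  }
  g
}

## loss value and logit gradient for one image
unetLoss <- function(probs, target, loss) {
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  y <- target
  n <- length(p)
  val <- 0; dZ <- 0
  if (loss %in% c("bce", "bcedice")) {
    val <- val - mean(y * log(p) + (1 - y) * log(1 - p))
    dZ <- dZ + (p - y) / n
  }
  if (loss %in% c("dice", "bcedice")) {
    s <- 1
    num <- 2 * sum(p * y) + s
    den <- sum(p) + sum(y) + s
    val <- val + 1 - num / den
    dDice_dp <- (2 * y * den - num) / den^2
    dZ <- dZ - dDice_dp * p * (1 - p)
  }
  list(value = val, dZ = dZ)
}

## elementwise tree arithmetic over parameter lists
mapParams <- function(f, ...) {
  lists <- list(...)
  rec <- function(...) {
    args <- list(...)
    if (is.list(args[[1]])) do.call(Map, c(list(rec), args)) else do.call(f, args)
  }
  do.call(rec, lists)
}

#' Train a U-Net stage
#'
#' Minibatch Adam on the configured loss. Training is fully seeded (one
#' stream drives shuffling), so a fixed config and seed reproduce the same
#' loss history and parameters on one machine. Inputs are min-max
#' normalized to [0, 1] per image before entering the network; masks must
#' be binary.
#'
#' @param model a [UNetModel-class] from [buildUNet()].
#' @param images list of numeric matrices (resized to the config input size
#'   if needed, bilinear).
#' @param masks list of binary matrices, same length (nearest-neighbor
#'   resize).
#' @param epochs,batchSize,learningRate optional overrides of the model
#'   config.
#' @return A list: `model` (trained [UNetModel-class]) and `history`
#'   (numeric vector of mean per-epoch loss).
#' @export
trainUNet <- function(model, images, masks, epochs = NULL, batchSize = NULL,
                      learningRate = NULL) {
  stopifnot(is(model, "UNetModel"), length(images) == length(masks))
  if (length(images) == 0L) stop("empty training set")
  cfg <- model@config
  epochs <- epochs %||% cfg@epochs
  batchSize <- batchSize %||% cfg@batchSize
  lr <- learningRate %||% cfg@learningRate
  sz <- cfg@inputSize
  images <- lapply(images, function(m) normalize01(resizeImage(m, sz, "bilinear")))
  masks <- lapply(masks, function(m) {
    m <- resizeImage(m + 0, sz, "nearest")
    (m > 0.5) + 0
  })
  set.seed(cfg@seed + 1L)
  p <- model@params
  mState <- mapParams(function(w) w * 0, p)
  vState <- mapParams(function(w) w * 0, p)
  t0 <- 0L
  history <- numeric(epochs)
  nImg <- length(images)
  for (ep in seq_len(epochs)) {
    ord <- sample(nImg)
    epochLoss <- 0
    for (start in seq(1L, nImg, by = batchSize)) {
      batch <- ord[start:min(start + batchSize - 1L, nImg)]
      grad <- NULL
      for (ix in batch) {
        fw <- unetForward(new("UNetModel", config = cfg, params = p),
                          images[[ix]], keep = TRUE)
        ls <- unetLoss(fw$probs, masks[[ix]], cfg@loss)
        epochLoss <- epochLoss + ls$value
        gi <- unetBackward(new("UNetModel", config = cfg, params = p),
                           fw$cache, ls$dZ)
        grad <- if (is.null(grad)) gi else
          mapParams(function(a, b) a + b, grad, gi)
      }
      grad <- mapParams(function(gq) gq / length(batch), grad)
      t0 <- t0 + 1L
      beta1 <- 0.9; beta2 <- 0.999; adEps <- 1e-8
      mState <- mapParams(function(m, gq) beta1 * m + (1 - beta1) * gq,
                          mState, grad)
      vState <- mapParams(function(v, gq) beta2 * v + (1 - beta2) * gq^2,
                          vState, grad)
      corr1 <- 1 - beta1^t0; corr2 <- 1 - beta2^t0
      p <- mapParams(function(w, m, v)
        w - lr * (m / corr1) / (sqrt(v / corr2) + adEps), p, mState, vState)
    }
    history[ep] <- epochLoss / nImg
  }
  list(model = new("UNetModel", config = cfg, params = p), history = history)
}

normalize01 <- function(m) {
  r <- range(m)
  if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
}

#' Predict an uncertainty heatmap
#'
#' The image is min-max normalized, resized to the network input size if
#' needed, passed through the network, and the probability map is resized
#' back to the original dimensions (bilinear).
#'
#' @param model a trained [UNetModel-class].
#' @param image numeric matrix.
#' @param threshold threshold stored with the prediction (default 0.5).
#' @return A [HeatmapPrediction-class] with the image's dimensions.
#' @export
predictHeatmap <- function(model, image, threshold = 0.5) {
  stopifnot(is(model, "UNetModel"))
  sz <- model@config@inputSize
  x <- normalize01(resizeImage(image, sz, "bilinear"))
  pr <- unetForward(model, x)$probs
  pr <- resizeImage(pr, dim(image), "bilinear")
  pr <- pmin(pmax(pr, 0), 1)
  new("HeatmapPrediction", probs = pr, threshold = threshold)
}

#' Binarize a heatmap
#'
#' Pixels with probability >= threshold are foreground; lowering the
#' threshold can only grow the mask (monotonicity).
#'
#' @param heatmap a [HeatmapPrediction-class] or probability matrix.
#' @param threshold override of the stored threshold.
#' @return A logical matrix.
#' @export
binarizeHeatmap <- function(heatmap, threshold = NULL) {
  if (is(heatmap, "HeatmapPrediction")) {
    thr <- threshold %||% heatmap@threshold
    heatmap@probs >= thr
  } else {
    heatmap >= (threshold %||% 0.5)
  }
}

#' Save / load a U-Net model
#'
#' The model (parameters plus embedded config) is stored as a single RDS
#' archive.
#'
#' @param model a [UNetModel-class].
#' @param path file path.
#' @return `path` invisibly (save); the [UNetModel-class] (load).
#' @export
saveUNet <- function(model, path) {
  stopifnot(is(model, "UNetModel"))
  saveRDS(list(config = list(depth = model@config@depth,
                             baseFilters = model@config@baseFilters,
                             inputSize = model@config@inputSize,
                             loss = model@config@loss,
                             epochs = model@config@epochs,
                             batchSize = model@config@batchSize,
                             learningRate = model@config@learningRate,
                             seed = model@config@seed),
               params = model@params), path)
  invisible(path)
}

#' @rdname saveUNet
#' @export
loadUNet <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(uNetConfig, x$config)
  new("UNetModel", config = cfg, params = x$params)
}
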