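#' Construct a ZStack
#'
#' @param voxels 3D array (z, y, x) of non-negative intensities; a matrix is
#'   promoted to a single-slice stack.
#' @param voxelSize numeric(3) (dz, dy, dx) in micrometres.
#' @param bitDepth 8 or 16.
#' @return A [ZStack-class].
#' @export
ZStack <- function(voxels, voxelSize = c(1, 1, 1), bitDepth = 16L) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  new("ZStack", voxels = voxels, voxelSize = as.numeric(voxelSize),
      bitDepth = as.integer(bitDepth))
}

#' Construct an Image2D
#'
#' @param pixels numeric matrix (y, x).
#' @param pixelSize numeric(2) (dy, dx) in micrometres.
#' @return An [Image2D-class].
#' @export
Image2D <- function(pixels, pixelSize = c(1, 1)) {
  new("Image2D", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Construct a TriLevelMask
#'
#' @param pixels numeric matrix over \{0, 128, 255\}.
#' @param pixelSize numeric(2) (dy, dx) in micrometres.
#' @return A [TriLevelMask-class].
#' @export
TriLevelMask <- function(pixels, pixelSize = c(1, 1)) {
  new("TriLevelMask", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Construct an HWatershedParams
#'
#' @param h dynamics threshold (>= 0).
#' @param hRelative if TRUE, `h` is a fraction of the per-image feature range.
#' @param intensityThreshold intensity floor for region pixels, absolute or
#'   relative to the feature range (see `intensityRelative`).
#' @param intensityRelative if TRUE, the floor is a fraction of the masked
#'   feature range above its minimum.
#' @param peakFlooding percent of each peak height flooded, in (0, 100].
#' @return An [HWatershedParams-class].
#' @export
hWatershedParams <- function(h = 0.05, hRelative = TRUE,
                             intensityThreshold = 0.25,
                             intensityRelative = TRUE, peakFlooding = 30) {
  new("HWatershedParams", h = h, hRelative = hRelative,
      intensityThreshold = intensityThreshold,
      intensityRelative = intensityRelative, peakFlooding = peakFlooding)
}

## ---- internal helpers ----

## 4-connected component labeling with consecutive labels.
## EBImage::bwlabel is 4-connected; relabel to 1..n in first-occurrence
## (column-major) order for determinism.
labelComponents <- function(mask) {
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask > 0), nrow(mask)))
  relabelConsecutive(matrix(as.integer(lab), nrow(mask)))
}

## renumber positive labels to consecutive 1..n, keeping first-occurrence order
relabelConsecutive <- function(lab) {
  pos <- lab > 0L
  if (!any(pos)) return(matrix(0L, nrow(lab), ncol(lab)))
  old <- unique(lab[pos])
  map <- integer(max(old))
  map[old] <- seq_along(old)
  out <- lab
  out[pos] <- map[lab[pos]]
  matrix(as.integer(out), nrow(lab))
}

## fill holes of a binary mask (holes = background components not reaching
## the image border)
fillMaskHoles <- function(mask) {
  filled <- EBImage::fillHull(matrix(as.numeric(mask > 0), nrow(mask)))
  matrix(filled > 0, nrow(mask))
}

## per-label pixel areas, named by label
labelAreas <- function(lab) {
  pos <- lab[lab > 0L]
  if (!length(pos)) return(setNames(integer(0), character(0)))
  table(pos)
}

## centroids (y, x) of labels 1..n
labelCentroids <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x"))))
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  cy <- tapply(idx[, 1], l, mean)
  cx <- tapply(idx[, 2], l, mean)
  out <- cbind(y = as.numeric(cy), x = as.numeric(cx))
  out[order(as.integer(names(cy))), , drop = FALSE]
}

## Gaussian kernel, radius ceil(3*sigma), normalized
gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## derivative-of-Gaussian kernel (d/dx of the Gaussian), radius ceil(3*sigma)
gaussDerivKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  -x / sigma^2 * g
}

## reflect-pad indices for length n and pad r: (r)(r-1)...1 | 1..n | n..(n-r+1)
reflectIndex <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  left <- pmin(rev(seq_len(r)), n)
  right <- pmax(n + 1L - seq_len(r), 1L)
  c(left, seq_len(n), right)
}

## separable 1D convolution of a 3D array along one axis with reflection
## padding; kernel length 2r+1. Fully vectorized as a sum of shifted slabs.
convolveAxis3d <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) %/% 2L
  n <- d[axis]
  idx <- reflectIndex(n, r)
  pad <- switch(axis,
                arr[idx, , , drop = FALSE],
                arr[, idx, , drop = FALSE],
                arr[, , idx, drop = FALSE])
  out <- array(0, d)
  for (k in seq_along(kernel)) {
    take <- (k - 1L) + seq_len(n)
    slab <- switch(axis,
                   pad[take, , , drop = FALSE],
                   pad[, take, , drop = FALSE],
                   pad[, , take, drop = FALSE])
    out <- out + kernel[k] * slab
  }
  out
}

## 2D separable convolution with reflection padding
convolve2dSep <- function(m, kernel) {
  a <- array(m, c(dim(m), 1L))
  a <- convolveAxis3d(a, kernel, 1L)
  a <- convolveAxis3d(a, kernel, 2L)
  a[, , 1]
}

## local maxima of a 2D image within a mask, with a minimum separation:
## candidates are pixels equal to the max over their (2r+1)^2 neighborhood
## (r grows with minSep so ridge saddles are not picked up), then greedily
## kept in decreasing intensity order if no kept peak lies closer than
## minSep. Returns (y, x) integer matrix.
localMaxima2d <- function(m, minSep, mask = NULL) {
  r <- max(1L, min(7L, as.integer(floor(minSep / 2))))
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2L * r, w + 2L * r)
  pad[r + seq_len(h), r + seq_len(w)] <- m
  mx <- matrix(-Inf, h, w)
  for (dy in -r:r) for (dx in -r:r) {
    mx <- pmax(mx, pad[r + dy + seq_len(h), r + dx + seq_len(w)])
  }
  cand <- which(m == mx & (if (is.null(mask)) TRUE else mask), arr.ind = TRUE)
  if (nrow(cand) == 0L) return(cand)
  ord <- order(m[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0L ||
        min(sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2)) >= minSep) {
      keep[i] <- TRUE
      kept <- rbind(kept, p)
    }
  }
  cand[keep, , drop = FALSE]
}

## resize a (y, x) matrix to newDim = c(H, W); EBImage's first dim is x,
## but since we pass matrices as-is and request w = rows, the mapping is
## consistent both ways.
resizeImage <- function(m, newDim, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (all(dim(m) == newDim)) return(m)
  out <- EBImage::resize(m, w = newDim[1], h = newDim[2],
                         filter = if (method == "bilinear") "bilinear" else "none")
  matrix(out, newDim[1], newDim[2])
}

## stop unless x is a single non-negative integer-ish number
checkCount <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(what, " must be a single non-negative integer", call. = FALSE)
  invisible(as.integer(x))
}
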