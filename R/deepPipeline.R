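#' Seeded augmentation of an image/mask pair
#'
#' Draws `multiplicity` augmented copies (the first is always the original
#' pair). Geometric transforms (horizontal/vertical flips, 90-degree
#' rotations, small free rotations) are applied identically to image and
#' mask, the mask with nearest-neighbor interpolation so it stays binary;
#' photometric transforms (intensity scale, gamma, additive Gaussian noise)
#' touch the image only.
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same shape.
#' @param multiplicity number of pairs returned (>= 1).
#' @param seed RNG seed.
#' @param ops character subset of c("flip", "rot90", "rotate", "intensity",
#'   "noise"); empty disables augmentation (originals are replicated).
#' @return List of `multiplicity` lists with elements `image` and `mask`.
#' @export
augmentPair <- function(image, mask, multiplicity = 1, seed = 1,
                        ops = c("flip", "rot90", "rotate", "intensity",
                                "noise")) {
  stopifnot(all(dim(image) == dim(mask)), multiplicity >= 1)
  set.seed(seed)
  out <- vector("list", multiplicity)
  out[[1]] <- list(image = image, mask = (mask > 0) + 0)
  if (multiplicity == 1) return(out)
  for (k in 2:multiplicity) {
    img <- image; msk <- (mask > 0) + 0
    if ("flip" %in% ops && runif(1) < 0.5) {
      img <- img[nrow(img):1, ]; msk <- msk[nrow(msk):1, ]
    }
    if ("flip" %in% ops && runif(1) < 0.5) {
      img <- img[, ncol(img):1]; msk <- msk[, ncol(msk):1]
    }
    if ("rot90" %in% ops) {
      r <- sample(0:3, 1)
      if (r > 0) for (q in seq_len(r)) {
        img <- t(img[nrow(img):1, ]); msk <- t(msk[nrow(msk):1, ])
      }
    }
    if ("rotate" %in% ops && runif(1) < 0.5) {
      ang <- runif(1, -15, 15)
      img <- matrix(EBImage::rotate(img, ang, output.dim = dim(img),
                                    bg.col = min(img)), nrow(img))
      msk <- matrix(EBImage::rotate(msk, ang, output.dim = dim(msk),
                                    filter = "none", bg.col = 0), nrow(msk))
      msk <- (msk > 0.5) + 0
    }
    if ("intensity" %in% ops) {
      img <- img * runif(1, 0.8, 1.2)
      rng <- range(img)
      if (rng[2] > rng[1]) {
        u <- (img - rng[1]) / (rng[2] - rng[1])
        img <- rng[1] + (rng[2] - rng[1]) * u^runif(1, 0.8, 1.25)
      }
    }
    if ("noise" %in% ops) {
      img <- img + rnorm(length(img), sd = 0.02 * max(1e-12, diff(range(img))))
    }
    out[[k]] <- list(image = img, mask = msk)
  }
  out
}

## grow a bounding box (y0, y1, x0, x1 inclusive) by a fractional margin
growBox <- function(box, marginFrac, dims) {
  my <- round(marginFrac * (box[2] - box[1] + 1L))
  mx <- round(marginFrac * (box[4] - box[3] + 1L))
  c(max(1L, box[1] - my), min(dims[1], box[2] + my),
    max(1L, box[3] - mx), min(dims[2], box[4] + mx))
}

#' Extract per-nucleus training fragments from ground-truth labels
#'
#' Crops each labeled nucleus with a fractional margin and resizes image
#' (bilinear) and masks (nearest) to a common fragment size; the
#' ground-truth-box counterpart of [proposeRegions()] used to train the
#' nucleus and chromocenter stages.
#'
#' @param image numeric matrix (projection).
#' @param nucleusLabels integer label matrix.
#' @param ccLabels optional chromocenter label matrix.
#' @param size integer(2) fragment size, default c(64, 64).
#' @param marginFrac fractional margin per side, default 0.15.
#' @return List with one element per nucleus: `image`, `nucleusMask`,
#'   `ccMask` (NULL when no ccLabels), `box` (y0, y1, x0, x1 inclusive) and
#'   `label`.
#' @export
extractFragments <- function(image, nucleusLabels, ccLabels = NULL,
                             size = c(64L, 64L), marginFrac = 0.15) {
  stopifnot(all(dim(image) == dim(nucleusLabels)))
  n <- max(nucleusLabels)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(nucleusLabels == k, arr.ind = TRUE)
    box <- growBox(c(min(idx[, 1]), max(idx[, 1]),
                     min(idx[, 2]), max(idx[, 2])), marginFrac,
                   dim(image))
    sub <- image[box[1]:box[2], box[3]:box[4]]
    nm <- (nucleusLabels[box[1]:box[2], box[3]:box[4]] == k) + 0
    frag <- list(
      image = resizeImage(sub, size, "bilinear"),
      nucleusMask = (resizeImage(nm, size, "nearest") > 0.5) + 0,
      ccMask = NULL, box = box, label = k)
    if (!is.null(ccLabels)) {
      cm <- ((ccLabels[box[1]:box[2], box[3]:box[4]] > 0) & (nm > 0)) + 0
      frag$ccMask <- (resizeImage(cm, size, "nearest") > 0.5) + 0
    }
    out[[k]] <- frag
  }
  out
}

#' Training target for the region-proposal stage
#'
#' The region-proposal U-Net is trained on the binary union of dilated
#' nucleus masks, so that thresholding its heatmap yields one blob (and
#' hence one bounding box) per nucleus.
#'
#' @param nucleusLabels integer label matrix.
#' @param dilate dilation radius in pixels (default 3).
#' @return A binary matrix.
#' @export
regionProposalTarget <- function(nucleusLabels, dilate = 3) {
  m <- (nucleusLabels > 0) + 0
  if (dilate > 0) {
    kern <- EBImage::makeBrush(2 * dilate + 1, shape = "disc")
    m <- matrix(EBImage::dilate(m, kern), nrow(m))
  }
  (m > 0) + 0
}

#' Propose single-nucleus regions with the region-proposal U-Net
#'
#' The heatmap is binarized at `threshold`, connected components become
#' bounding boxes (expanded by `marginFrac`, clipped to the image), and
#' each box is cropped and resized to `fragmentSize`. An empty proposal set
#' is a valid result.
#'
#' @param image numeric matrix (projection).
#' @param rpModel trained region-proposal [UNetModel-class].
#' @param threshold heatmap threshold, default 0.5.
#' @param marginFrac fractional box margin per side, default 0.15.
#' @param fragmentSize integer(2) fragment size handed to the nucleus
#'   stage, default the rp model input size.
#' @param minArea discard proposal blobs smaller than this (default 20 px).
#' @return List with `fragments` (list of matrices), `boxes` (n x 4 matrix,
#'   y0, y1, x0, x1 inclusive) and `heatmap` (the
#'   [HeatmapPrediction-class]).
#' @export
proposeRegions <- function(image, rpModel, threshold = 0.5,
                           marginFrac = 0.15, fragmentSize = NULL,
                           minArea = 20) {
  hm <- predictHeatmap(rpModel, image, threshold)
  fragmentSize <- fragmentSize %||% rpModel@config@inputSize
  bin <- binarizeHeatmap(hm)
  lab <- removeSmall(labelComponents(bin), minArea)
  n <- max(lab)
  boxes <- matrix(0L, n, 4,
                  dimnames = list(NULL, c("y0", "y1", "x0", "x1")))
  frags <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    box <- growBox(c(min(idx[, 1]), max(idx[, 1]),
                     min(idx[, 2]), max(idx[, 2])), marginFrac, dim(image))
    boxes[k, ] <- box
    frags[[k]] <- resizeImage(image[box[1]:box[2], box[3]:box[4]],
                              fragmentSize, "bilinear")
  }
  list(fragments = frags, boxes = boxes, heatmap = hm)
}

#' Run the full three-stage cascade on one projection
#'
#' Region proposal -> per-fragment nucleus heatmap -> per-fragment
#' chromocenter heatmap. Fragment probability maps are mapped back to
#' original coordinates through the inverse resize and merged across
#' overlapping fragments by pixelwise maximum; the merged maps are
#' binarized at the two thresholds (chromocenters additionally masked to
#' nuclei) and composed into a tri-level mask.
#'
#' @param image numeric matrix (max projection of the stack).
#' @param rpModel,nucModel,ccModel trained [UNetModel-class] stages.
#' @param thresholds numeric(2), (nucleus, chromocenter); default
#'   c(0.5, 0.5). Documented presets: c(0.5, 0.25) and c(0.8, 0.2).
#' @param marginFrac proposal box margin, default 0.15.
#' @return List: `trilevel` ([TriLevelMask-class]), `nucleusProbs` and
#'   `ccProbs` ([HeatmapPrediction-class] over the full image), `boxes`.
#' @export
predictTrilevel <- function(image, rpModel, nucModel, ccModel,
                            thresholds = c(0.5, 0.5), marginFrac = 0.15) {
  stopifnot(length(thresholds) == 2)
  prop <- proposeRegions(image, rpModel, marginFrac = marginFrac,
                         fragmentSize = nucModel@config@inputSize)
  if (!all(nucModel@config@inputSize == ccModel@config@inputSize))
    stop("nucleus and chromocenter models have incompatible input sizes")
  nucFull <- matrix(0, nrow(image), ncol(image))
  ccFull <- matrix(0, nrow(image), ncol(image))
  for (k in seq_along(prop$fragments)) {
    b <- prop$boxes[k, ]
    subDim <- c(b[2] - b[1] + 1L, b[4] - b[3] + 1L)
    np <- probs(predictHeatmap(nucModel, prop$fragments[[k]]))
    cp <- probs(predictHeatmap(ccModel, prop$fragments[[k]]))
    npBack <- pmin(pmax(resizeImage(np, subDim, "bilinear"), 0), 1)
    cpBack <- pmin(pmax(resizeImage(cp, subDim, "bilinear"), 0), 1)
    ys <- b[1]:b[2]; xs <- b[3]:b[4]
    nucFull[ys, xs] <- pmax(nucFull[ys, xs], npBack)
    ccFull[ys, xs] <- pmax(ccFull[ys, xs], cpBack)
  }
  nucMask <- nucFull >= thresholds[1]
  ccMask <- (ccFull >= thresholds[2]) & nucMask
  list(trilevel = composeTrilevel(nucMask, ccMask),
       nucleusProbs = new("HeatmapPrediction", probs = nucFull,
                          threshold = thresholds[1]),
       ccProbs = new("HeatmapPrediction", probs = ccFull,
                     threshold = thresholds[2]),
       boxes = prop$boxes)
}
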