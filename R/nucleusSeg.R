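#' Minimum cross-entropy threshold (Li & Lee)
#'
#' Exhaustively scans every candidate threshold (the distinct pixel values
#' below the image maximum) and returns the one minimizing the cross entropy
#' between the image and its two-level reconstruction by below/above-class
#' means. With class sums m1 = sum(g * h(g)) and class means mu, the
#' minimized objective is -m1_low * log(mu_low) - m1_high * log(mu_high)
#' (the g*log(g) term is threshold-independent). Foreground is `pixels >
#' threshold`. Ties are broken toward the lower threshold, so the result is
#' deterministic.
#'
#' @param image an [Image2D-class] (or numeric matrix) with at least two
#'   distinct values.
#' @return The threshold, one of the image's pixel values.
#' @export
minCrossEntropyThreshold <- function(image) {
  g <- if (is(image, "Image2D")) image@pixels else image
  g <- as.vector(g)
  if (any(g < 0)) stop("intensities must be non-negative")
  vals <- sort(unique(g))
  if (length(vals) < 2L) stop("degenerate histogram: image is constant")
  h <- as.numeric(table(factor(g, levels = vals)))
  gh <- vals * h
  cs_h <- cumsum(h)
  cs_gh <- cumsum(gh)
  n <- length(vals)
  # candidates: thresholds at vals[1..n-1]; low class = values <= t
  i <- seq_len(n - 1L)
  m0L <- cs_h[i];  m1L <- cs_gh[i]
  m0H <- cs_h[n] - m0L; m1H <- cs_gh[n] - m1L
  muL <- ifelse(m0L > 0, m1L / m0L, 0)
  muH <- ifelse(m0H > 0, m1H / m0H, 0)
  termL <- ifelse(m1L > 0, -m1L * log(muL), 0)
  termH <- ifelse(m1H > 0, -m1H * log(muH), 0)
  vals[which.min(termL + termH)]
}

## drop labels with area < minArea and renumber
removeSmall <- function(lab, minArea) {
  if (max(lab) == 0L) return(lab)
  ar <- tabulate(lab[lab > 0L])
  small <- which(ar < minArea)
  if (length(small)) lab[lab %in% small] <- 0L
  relabelConsecutive(lab)
}

#' Detect nuclei on a 2D projection
#'
#' The classical detector: median-filter the projection, threshold with
#' [minCrossEntropyThreshold()], fill holes, label 4-connected components,
#' discard regions smaller than `minArea`, and (optionally) split touching
#' nuclei by growing markers placed at local maxima of the Euclidean
#' distance transform (minimum marker separation 0.5 * sqrt(minArea)).
#'
#' @param projection an [Image2D-class], typically from [zProject()].
#' @param medianRadius median filter disk radius in pixels (default 2).
#' @param minArea minimum nucleus area in pixels (default 500).
#' @param splitTouching split merged nuclei through the watershed-style
#'   marker growing step (default TRUE).
#' @param fillHoles fill holes inside nuclei (default TRUE).
#' @return A [RoiSet-class]; every label is tagged "auto".
#' @export
detectNuclei <- function(projection, medianRadius = 2, minArea = 500,
                         splitTouching = TRUE, fillHoles = TRUE) {
  stopifnot(is(projection, "Image2D"))
  filt <- medianFilter2D(projection, medianRadius)
  thr <- minCrossEntropyThreshold(filt)
  bin <- filt@pixels > thr
  if (fillHoles) bin <- fillMaskHoles(bin)
  lab <- labelComponents(bin)
  lab <- removeSmall(lab, minArea)
  if (splitTouching && max(lab) > 0L) {
    bin2 <- lab > 0L
    dm <- EBImage::distmap(matrix(as.numeric(bin2), nrow(bin2)))
    dm <- matrix(dm, nrow(bin2))
    peaks <- localMaxima2d(dm, minSep = 0.5 * sqrt(minArea), mask = bin2)
    if (nrow(peaks) >= 1L) {
      seeds <- matrix(0L, nrow(bin2), ncol(bin2))
      seeds[peaks] <- seq_len(nrow(peaks))
      # large lambda: growth cost is dominated by spatial distance, so the
      # markers split the blob along the (Voronoi) neck bisector
      grown <- EBImage::propagate(dm, seeds = seeds, mask = bin2,
                                  lambda = 1e6)
      lab <- relabelConsecutive(matrix(as.integer(grown), nrow(bin2)))
      lab <- removeSmall(lab, minArea)
    }
  }
  new("RoiSet", labelImage = lab,
      provenance = rep("auto", max(lab)), minArea = minArea)
}

## rasterize a simple polygon (vertices as (y, x) rows, pixel-center
## even-odd rule) into a logical matrix of the given dimensions
rasterizePolygon <- function(poly, dims) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  out <- matrix(FALSE, dims[1], dims[2])
  ys <- poly[, 1]; xs <- poly[, 2]
  ny <- nrow(poly)
  jend <- c(2:ny, 1L)
  y0 <- max(1L, floor(min(ys))); y1 <- min(dims[1], ceiling(max(ys)))
  for (row in y0:y1) {
    cross <- numeric(0)
    for (e in seq_len(ny)) {
      ya <- ys[e]; yb <- ys[jend[e]]
      if ((ya <= row && yb > row) || (yb <= row && ya > row)) {
        tfrac <- (row - ya) / (yb - ya)
        cross <- c(cross, xs[e] + tfrac * (xs[jend[e]] - xs[e]))
      }
    }
    cross <- sort(cross)
    if (length(cross) >= 2L) {
      for (k in seq(1L, length(cross) - 1L, by = 2L)) {
        xa <- ceiling(cross[k]); xb <- floor(cross[k + 1])
        if (xb >= xa)
          out[row, max(1L, xa):min(dims[2], xb)] <- TRUE
      }
    }
  }
  out
}

#' Apply a file-based curation edit to a RoiSet
#'
#' Scriptable replacement for interactive curation: wrongly detected nuclei
#' are removed by label id, missed nuclei are added as polygons rasterized
#' into new regions tagged "added". Labels are renumbered consecutively,
#' remaining regions first (in their previous order), added regions last.
#'
#' @param rois a [RoiSet-class].
#' @param edit a list with elements `removals` (integer label ids) and
#'   `additions` (list of polygons, each an n x 2 matrix of (y, x)
#'   vertices); see [readCurationEdit()] for the JSON form.
#' @return The curated [RoiSet-class].
#' @export
applyCuration <- function(rois, edit) {
  stopifnot(is(rois, "RoiSet"))
  removals <- as.integer(edit$removals %||% integer(0))
  additions <- edit$additions %||% list()
  n <- nLabels(rois)
  if (length(removals) && !all(removals %in% seq_len(n)))
    stop("curation removal id absent from RoiSet: ",
         paste(setdiff(removals, seq_len(n)), collapse = ", "))
  lab <- rois@labelImage
  lab[lab %in% removals] <- 0L
  keepTags <- rois@provenance[setdiff(seq_len(n), removals)]
  lab <- relabelConsecutive(lab)
  tags <- keepTags
  for (poly in additions) {
    px <- rasterizePolygon(poly, dim(lab))
    if (any(lab[px] > 0L))
      stop("added polygon overlaps an existing nucleus")
    lab[px] <- max(lab) + 1L
    tags <- c(tags, "added")
  }
  new("RoiSet", labelImage = lab, provenance = tags, minArea = rois@minArea)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a curation edit from JSON
#'
#' Format: `{"removals": [2], "additions": [[[y, x], ...], ...]}` with
#' 1-based pixel coordinates.
#'
#' @param path JSON file path.
#' @return A list suitable for [applyCuration()].
#' @export
readCurationEdit <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  adds <- lapply(j$additions, function(p) {
    m <- do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    if (is.null(m) || ncol(m) != 2L)
      stop("curation polygon must be a list of (y, x) vertex pairs")
    colnames(m) <- c("y", "x")
    m
  })
  list(removals = as.integer(unlist(j$removals)), additions = adds)
}

#' Crop the sub-stack around one nucleus
#'
#' The bounding box of the region is expanded by `marginFrac` of its height
#' (width) on each side, clipped to the image bounds; all z slices are kept.
#'
#' @param stack the original [ZStack-class].
#' @param rois a [RoiSet-class] on the stack's projection.
#' @param label the nucleus label to crop.
#' @param marginFrac fractional margin per side (default 0).
#' @return A list with `stack` (the cropped [ZStack-class]), `mask` (logical
#'   matrix of the nucleus within the crop) and `box`
#'   (c(y0, y1, x0, x1), inclusive).
#' @export
cropNucleus <- function(stack, rois, label, marginFrac = 0) {
  stopifnot(is(stack, "ZStack"), is(rois, "RoiSet"))
  lab <- rois@labelImage
  if (!label %in% lab) stop("label ", label, " absent from RoiSet")
  idx <- which(lab == label, arr.ind = TRUE)
  y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
  x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
  my <- as.integer(round(marginFrac * (y1 - y0 + 1L)))
  mx <- as.integer(round(marginFrac * (x1 - x0 + 1L)))
  d <- dim(stack@voxels)
  y0 <- max(1L, y0 - my); y1 <- min(as.integer(d[2]), y1 + my)
  x0 <- max(1L, x0 - mx); x1 <- min(as.integer(d[3]), x1 + mx)
  sub <- stack@voxels[, y0:y1, x0:x1, drop = FALSE]
  ZStackSub <- ZStack(sub, voxelSize = stack@voxelSize,
                      bitDepth = stack@bitDepth)
  list(stack = ZStackSub, mask = lab[y0:y1, x0:x1] == label,
       box = c(y0 = y0, y1 = y1, x0 = x0, x1 = x1))
}
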