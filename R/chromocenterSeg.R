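#' TensorFeatureStack: largest structure-tensor eigenvalue per voxel
#'
#' @slot values 3D array (z, y, x) of the largest eigenvalue of the local
#'   structure tensor; non-negative by construction.
#' @slot sigmaGrad Gaussian derivative scale in pixels.
#' @slot sigmaInt tensor integration (smoothing) scale in pixels.
#' @export
setClass("TensorFeatureStack",
  representation(values = "array", sigmaGrad = "numeric",
                 sigmaInt = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be 3D")
    if (any(object@values < -1e-9)) return("eigenvalues must be >= 0")
    TRUE
  })

## largest eigenvalue of a field of symmetric 3x3 matrices, analytic
## (trigonometric) form, fully vectorized; components as equal-shaped arrays
largestEig3 <- function(xx, yy, zz, xy, xz, yz) {
  q <- (xx + yy + zz) / 3
  p2 <- ((xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)) / 6
  p <- sqrt(pmax(p2, 0))
  bxx <- xx - q; byy <- yy - q; bzz <- zz - q
  detB <- bxx * (byy * bzz - yz^2) - xy * (xy * bzz - yz * xz) +
    xz * (xy * yz - byy * xz)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  out <- ifelse(p > 0, q + 2 * p * cos(phi), q)
  pmax(out, 0)
}

#' Largest 3D structure-tensor eigenvalue feature
#'
#' At each voxel the intensity gradient is estimated with Gaussian
#' derivatives at scale `sigmaGrad` (the z component rescaled by dx/dz to
#' compensate voxel anisotropy), the gradient outer-product tensor is
#' smoothed componentwise at scale `sigmaInt`, and its largest eigenvalue is
#' returned. The feature highlights strong local intensity variation and is
#' the input of the chromocenter watershed. Single-slice stacks degenerate
#' gracefully to the 2D tensor (zero z gradient).
#'
#' @param substack a [ZStack-class] (typically a nucleus crop).
#' @param sigmaGrad derivative scale in pixels (> 0), default 1.
#' @param sigmaInt integration scale in pixels (> 0), default 1.5 (of the
#'   order of the smallest foci to be enhanced).
#' @return A [TensorFeatureStack-class].
#' @export
structureTensorMaxEig <- function(substack, sigmaGrad = 1, sigmaInt = 1.5) {
  stopifnot(is(substack, "ZStack"))
  if (sigmaGrad <= 0 || sigmaInt <= 0) stop("scales must be positive")
  v <- substack@voxels
  g <- gaussKernel1d(sigmaGrad)
  dg <- gaussDerivKernel1d(sigmaGrad)
  aniso <- substack@voxelSize[3] / substack@voxelSize[1]  # dx / dz
  gx <- convolveAxis3d(convolveAxis3d(convolveAxis3d(v, dg, 3L), g, 2L), g, 1L)
  gy <- convolveAxis3d(convolveAxis3d(convolveAxis3d(v, dg, 2L), g, 3L), g, 1L)
  gz <- convolveAxis3d(convolveAxis3d(convolveAxis3d(v, dg, 1L), g, 2L), g, 3L) * aniso
  sm <- function(a) {
    a <- convolveAxis3d(a, gaussKernel1d(sigmaInt), 1L)
    a <- convolveAxis3d(a, gaussKernel1d(sigmaInt), 2L)
    convolveAxis3d(a, gaussKernel1d(sigmaInt), 3L)
  }
  jxx <- sm(gx * gx); jyy <- sm(gy * gy); jzz <- sm(gz * gz)
  jxy <- sm(gx * gy); jxz <- sm(gx * gz); jyz <- sm(gy * gz)
  eig <- largestEig3(jxx, jyy, jzz, jxy, jxz, jyz)
  new("TensorFeatureStack", values = array(eig, dim(v)),
      sigmaGrad = sigmaGrad, sigmaInt = sigmaInt)
}

#' Hierarchical (H-) watershed within a nucleus mask
#'
#' Batch re-implementation of the three interactive H-watershed controls:
#' intensity maxima whose dynamics (peak minus highest saddle towards a
#' higher peak) reach `h` seed a watershed flooding of the image; each
#' resulting region is then truncated to pixels with value at least
#' max(intensityThreshold, (1 - peakFlooding/100) * region peak). Labels
#' exist only inside the nucleus mask. The dynamics-based flooding is
#' delegated to EBImage's watershed with `tolerance = h`.
#'
#' @param image an [Image2D-class] or numeric matrix (the feature
#'   projection).
#' @param params an [HWatershedParams-class].
#' @param mask logical matrix, the nucleus mask; must be nonempty.
#' @return An integer label matrix, 0 outside chromocenters.
#' @export
hWatershed <- function(image, params = hWatershedParams(), mask = NULL) {
  img <- if (is(image, "Image2D")) image@pixels else image
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!any(mask)) stop("empty nucleus mask")
  stopifnot(all(dim(img) == dim(mask)))
  lo <- min(img[mask]); hi <- max(img[mask])
  rng <- hi - lo
  if (rng == 0) return(matrix(0L, nrow(img), ncol(img)))
  h <- if (params@hRelative) params@h * rng else params@h
  # the global maximum itself has dynamics equal to the masked range; an h
  # beyond it means no maximum qualifies as a seed at all
  if (rng < h) return(matrix(0L, nrow(img), ncol(img)))
  floorAbs <- if (params@intensityRelative)
    lo + params@intensityThreshold * rng else params@intensityThreshold
  eps <- rng * 1e-6
  work <- matrix(0, nrow(img), ncol(img))
  work[mask] <- img[mask] - lo + eps
  ws <- EBImage::watershed(work, tolerance = h, ext = 1)
  lab <- relabelConsecutive(matrix(as.integer(ws), nrow(img)))
  if (max(lab) == 0L) return(lab)
  pf <- params@peakFlooding
  for (k in seq_len(max(lab))) {
    sel <- lab == k
    peak <- max(img[sel])
    floor_k <- max(floorAbs, (1 - pf / 100) * peak)
    lab[sel & (img < floor_k)] <- 0L
  }
  ## a region whose own peak falls below the floor disappears entirely
  relabelConsecutive(lab)
}

#' Segment chromocenters inside every nucleus of a RoiSet
#'
#' For each nucleus: crop the surrounding sub-stack ([cropNucleus()]),
#' compute the largest structure-tensor eigenvalue
#' ([structureTensorMaxEig()]), z-project it, and run [hWatershed()] within
#' the nucleus mask. Per-nucleus results are pasted back into a full-image
#' chromocenter label image with globally consecutive labels. A failure in
#' one nucleus is logged as a warning and processing continues.
#'
#' Two batch guards stand in for the curation an interactive session would
#' provide: the feature is flattened in a thin band along the nucleus
#' boundary (`rimSuppress` pixels), because the nucleus edge itself is the
#' strongest gradient structure in the crop and otherwise seeds spurious
#' rim regions; and segmented regions smaller than `minCcArea` pixels are
#' discarded as texture speckle.
#'
#' @param stack the original [ZStack-class].
#' @param rois a nonempty [RoiSet-class].
#' @param params an [HWatershedParams-class]; the defaults (dynamics 5% of
#'   the per-nucleus feature range, floor at 10% of the range, 20% peak
#'   flooding) are calibrated for chromocenter-scale foci and all
#'   overridable.
#' @param sigmaGrad,sigmaInt structure tensor scales in pixels.
#' @param marginFrac crop margin per side (default 0.1).
#' @param projection z-projection applied to the feature stack, "max"
#'   (default) or "std".
#' @param rimSuppress width (px) of the boundary band in which the feature
#'   is flattened before the watershed; 0 disables it.
#' @param minCcArea minimum chromocenter region area in pixels.
#' @return A list: `ccLabels` (integer matrix over the full projection) and
#'   `nucleusOf` (integer vector mapping each chromocenter label to its
#'   nucleus label).
#' @export
segmentChromocenters <- function(stack, rois, params = hWatershedParams(),
                                 sigmaGrad = 1, sigmaInt = 1.5,
                                 marginFrac = 0.1,
                                 projection = c("max", "std"),
                                 rimSuppress = 3, minCcArea = 4) {
  stopifnot(is(stack, "ZStack"), is(rois, "RoiSet"))
  projection <- match.arg(projection)
  if (nLabels(rois) == 0L) stop("RoiSet is empty")
  d <- dim(stack@voxels)
  full <- matrix(0L, d[2], d[3])
  nucleusOf <- integer(0)
  for (k in seq_len(nLabels(rois))) {
    res <- tryCatch({
      crop <- cropNucleus(stack, rois, k, marginFrac)
      feat <- structureTensorMaxEig(crop$stack, sigmaGrad, sigmaInt)
      featStack <- ZStack(feat@values + 0, voxelSize = stack@voxelSize,
                          bitDepth = stack@bitDepth)
      projPx <- pixels(zProject(featStack, projection))
      m <- crop$mask
      if (rimSuppress > 0) {
        dm <- matrix(EBImage::distmap(matrix(as.numeric(m), nrow(m))),
                     nrow(m))
        band <- m & dm <= rimSuppress
        if (any(m & !band)) projPx[band] <- min(projPx[m & !band])
      }
      lab <- hWatershed(projPx, params, m)
      lab <- removeSmall(lab, minCcArea)
      list(lab = lab, box = crop$box)
    }, error = function(e) {
      warning("nucleus ", k, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res) || max(res$lab) == 0L) next
    off <- max(full)
    b <- res$box
    sub <- full[b["y0"]:b["y1"], b["x0"]:b["x1"]]
    sel <- res$lab > 0L
    sub[sel] <- res$lab[sel] + off
    full[b["y0"]:b["y1"], b["x0"]:b["x1"]] <- sub
    nucleusOf <- c(nucleusOf, rep(k, max(res$lab)))
  }
  list(ccLabels = full, nucleusOf = nucleusOf)
}
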