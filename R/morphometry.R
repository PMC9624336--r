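#' Compose a tri-level annotation mask
#'
#' Background 0, nucleus 128, chromocenter 255. Every chromocenter pixel
#' must lie inside the nucleus mask, otherwise an error is raised.
#'
#' @param nucleusMask logical (or 0/1) matrix of nucleus pixels.
#' @param ccLabels integer matrix (or logical) of chromocenter pixels.
#' @param pixelSize numeric(2), (dy, dx) in micrometres.
#' @return A [TriLevelMask-class].
#' @export
composeTrilevel <- function(nucleusMask, ccLabels, pixelSize = c(1, 1)) {
  nuc <- nucleusMask > 0
  cc <- ccLabels > 0
  stopifnot(all(dim(nuc) == dim(cc)))
  if (any(cc & !nuc))
    stop("chromocenter pixel outside nucleus mask")
  px <- matrix(0, nrow(nuc), ncol(nuc))
  px[nuc] <- 128
  px[cc] <- 255
  TriLevelMask(px, pixelSize = pixelSize)
}

#' Split a tri-level mask into label images
#'
#' Nucleus regions are the 4-connected components of (128 or 255) pixels;
#' chromocenter regions are the components of 255 pixels.
#'
#' @param trilevel a [TriLevelMask-class].
#' @return List with `nucleusLabels` and `ccLabels` integer matrices.
#' @export
trilevelToLabels <- function(trilevel) {
  stopifnot(is(trilevel, "TriLevelMask"))
  px <- trilevel@pixels
  list(nucleusLabels = labelComponents(px >= 128),
       ccLabels = labelComponents(px == 255))
}

#' Per-nucleus heterochromatin morphometrics
#'
#' Computes the standard DAPI heterochromatin parameters for one nucleus:
#' \itemize{
#'   \item nucleus area (physical units when the pixel size is known,
#'     pixel^2 otherwise);
#'   \item per-chromocenter relative area fractions
#'     RAF_i = area(CC_i) / area(nucleus);
#'   \item heterochromatin fraction HF = sum of chromocenter areas /
#'     nucleus area = sum(RAF);
#'   \item relative heterochromatin intensity RHI = mean chromocenter
#'     intensity / mean nucleus intensity (chromocenter pixels included in
#'     the nucleus mean);
#'   \item relative heterochromatin fraction RHF = HF x RHI, the proportion
#'     of stained DNA residing in chromocenters.
#' }
#' A nucleus without chromocenters gets HF = RHI = RHF = 0 (flagged by
#' ccCount = 0) rather than missing values, so downstream statistics never
#' drop nuclei silently.
#'
#' @param nucleusMask logical matrix, nonempty.
#' @param ccLabels integer matrix of chromocenter labels (pixels assumed
#'   inside the nucleus).
#' @param intensity an [Image2D-class] or matrix; by convention the maximum
#'   z-projection of the raw stack.
#' @param pixelSize numeric(2), (dy, dx) in micrometres; c(1, 1) reports
#'   pixel units.
#' @return A list: `nucleusArea`, `units` ("um2" or "px2"), `ccCount`,
#'   `raf` (numeric vector), `hf`, `rhi`, `rhf`.
#' @export
measureNucleus <- function(nucleusMask, ccLabels, intensity,
                           pixelSize = c(1, 1)) {
  nuc <- nucleusMask > 0
  if (!any(nuc)) stop("empty nucleus mask")
  img <- if (is(intensity, "Image2D")) intensity@pixels else intensity
  stopifnot(all(dim(nuc) == dim(img)), all(dim(nuc) == dim(ccLabels)))
  pxArea <- prod(pixelSize)
  units <- if (all(pixelSize == 1)) "px2" else "um2"
  nPix <- sum(nuc)
  cc <- ccLabels
  cc[!nuc] <- 0L
  ccIds <- sort(unique(cc[cc > 0L]))
  raf <- if (length(ccIds))
    as.numeric(tabulate(cc[cc > 0L])[ccIds]) / nPix else numeric(0)
  hf <- sum(raf)
  if (length(ccIds)) {
    rhi <- mean(img[cc > 0L]) / mean(img[nuc])
  } else rhi <- 0
  list(nucleusArea = nPix * pxArea, units = units,
       ccCount = length(ccIds), raf = raf, hf = hf, rhi = rhi,
       rhf = hf * rhi)
}

#' Batch morphometrics over a RoiSet or tri-level mask
#'
#' One record per nucleus, in label order, plus a long-format table of
#' per-chromocenter area fractions. Output is deterministic for identical
#' input.
#'
#' @param nuclei a [RoiSet-class], a [TriLevelMask-class] (chromocenter
#'   labels are derived from it) or an integer nucleus label matrix.
#' @param ccLabels integer chromocenter label matrix; ignored when `nuclei`
#'   is a tri-level mask.
#' @param intensity an [Image2D-class] or matrix (max z-projection of the
#'   raw stack by convention).
#' @param pixelSize numeric(2) (dy, dx) in micrometres.
#' @param image optional image name recorded in the tables.
#' @return List of two data.frames: `records` with columns image,
#'   nucleus_id, nucleus_area, units, cc_count, hf, rhi, rhf; and `raf`
#'   with columns image, nucleus_id, cc_index, raf.
#' @export
measureBatch <- function(nuclei, ccLabels = NULL, intensity,
                         pixelSize = c(1, 1), image = "") {
  if (is(nuclei, "TriLevelMask")) {
    labs <- trilevelToLabels(nuclei)
    nucLab <- labs$nucleusLabels
    ccLabels <- labs$ccLabels
    if (all(pixelSize == 1)) pixelSize <- nuclei@pixelSize
  } else if (is(nuclei, "RoiSet")) {
    nucLab <- nuclei@labelImage
  } else {
    nucLab <- nuclei
  }
  if (is.null(ccLabels)) stop("ccLabels required")
  img <- if (is(intensity, "Image2D")) intensity@pixels else intensity
  stopifnot(all(dim(nucLab) == dim(img)), all(dim(nucLab) == dim(ccLabels)))
  n <- max(nucLab)
  rows <- vector("list", n)
  rafRows <- vector("list", n)
  for (k in seq_len(n)) {
    m <- measureNucleus(nucLab == k, ccLabels, img, pixelSize)
    rows[[k]] <- data.frame(image = image, nucleus_id = k,
                            nucleus_area = m$nucleusArea, units = m$units,
                            cc_count = m$ccCount, hf = m$hf, rhi = m$rhi,
                            rhf = m$rhf, stringsAsFactors = FALSE)
    rafRows[[k]] <- if (m$ccCount > 0)
      data.frame(image = image, nucleus_id = k,
                 cc_index = seq_len(m$ccCount), raf = m$raf,
                 stringsAsFactors = FALSE)
    else NULL
  }
  list(records = do.call(rbind, rows) %||%
         data.frame(image = character(0), nucleus_id = integer(0),
                    nucleus_area = numeric(0), units = character(0),
                    cc_count = integer(0), hf = numeric(0),
                    rhi = numeric(0), rhf = numeric(0)),
       raf = do.call(rbind, rafRows) %||%
         data.frame(image = character(0), nucleus_id = integer(0),
                    cc_index = integer(0), raf = numeric(0)))
}

#' Write morphometric tables to CSV
#'
#' @param measures result of [measureBatch()].
#' @param path CSV path for the per-nucleus records.
#' @param rafPath optional CSV path for the long-format per-chromocenter
#'   area fractions; default `path` with a `_raf` suffix.
#' @return `path`, invisibly.
#' @export
writeMorphometrics <- function(measures, path, rafPath = NULL) {
  if (is.null(rafPath))
    rafPath <- sub("(\\.[^.]+)$", "_raf\\1", path)
  write.csv(measures$records, path, row.names = FALSE)
  write.csv(measures$raf, rafPath, row.names = FALSE)
  invisible(path)
}
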