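#' Read a single-channel multi-page TIFF z-stack
#'
#' Slices are taken in page order. Voxel size is resolved in priority order:
#' the `voxelSize` argument, then TIFF resolution metadata (x/y resolution
#' plus an ImageJ-style `spacing=` entry in the image description for dz),
#' then (1, 1, 1).
#'
#' @param path path to a grayscale 8- or 16-bit multi-page TIFF.
#' @param voxelSize optional numeric(3), (dz, dy, dx) in micrometres.
#' @return A [ZStack-class].
#' @export
readZStack <- function(path, voxelSize = NULL) {
  if (!file.exists(path)) stop("cannot read z-stack: file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("single channel required: ", path, " has multi-channel pages")
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  vs <- c(1, 1, 1)
  info <- attributes(pages[[1]])
  if (!is.null(info$x.resolution) && is.finite(info$x.resolution) &&
      info$x.resolution > 0) {
    vs[3] <- 1 / info$x.resolution
    vs[2] <- if (!is.null(info$y.resolution) && info$y.resolution > 0)
      1 / info$y.resolution else vs[3]
  }
  if (!is.null(info$description)) {
    m <- regmatches(info$description,
                    regexpr("spacing=[0-9.eE+-]+", info$description))
    if (length(m)) vs[1] <- as.numeric(sub("spacing=", "", m))
  }
  if (!is.null(voxelSize)) vs <- as.numeric(voxelSize)
  d <- dim(pages[[1]])
  vox <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  ZStack(vox, voxelSize = vs, bitDepth = as.integer(bits))
}

#' Write a ZStack as a multi-page TIFF
#'
#' Intensities are stored at the stack's bit depth; integer-valued stacks
#' roundtrip bit-identically through [readZStack()].
#'
#' @param stack a [ZStack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeZStack <- function(stack, path) {
  stopifnot(is(stack, "ZStack"))
  maxval <- 2^stack@bitDepth - 1
  if (max(stack@voxels) > maxval)
    stop("intensities exceed the stack bit depth")
  pages <- lapply(seq_len(dim(stack@voxels)[1]),
                  function(i) stack@voxels[i, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = stack@bitDepth)
  invisible(path)
}

#' Z-projection of a stack
#'
#' Collapses the z axis by pixelwise maximum or population (divide-by-N)
#' standard deviation, the two projections used ahead of nucleus detection.
#'
#' @param stack a [ZStack-class].
#' @param method "max" or "std".
#' @return An [Image2D-class] with pixel size (dy, dx) of the stack.
#' @export
zProject <- function(stack, method = c("max", "std")) {
  stopifnot(is(stack, "ZStack"))
  method <- match.arg(method)
  v <- stack@voxels
  nz <- dim(v)[1]
  if (method == "max") {
    px <- v[1, , ]
    if (nz > 1) for (i in 2:nz) px <- pmax(px, v[i, , ])
  } else {
    s1 <- v[1, , ]; s2 <- v[1, , ]^2
    if (nz > 1) for (i in 2:nz) { s1 <- s1 + v[i, , ]; s2 <- s2 + v[i, , ]^2 }
    px <- sqrt(pmax(s2 / nz - (s1 / nz)^2, 0))
  }
  Image2D(px, pixelSize = stack@voxelSize[2:3])
}

#' Median filter over a disk neighborhood
#'
#' Each pixel is replaced by the median over the disk of the given radius
#' (Euclidean distance <= radius); image edges are handled by reflection.
#' Radius 0 is the identity.
#'
#' @param image an [Image2D-class].
#' @param radius non-negative integer radius in pixels.
#' @return The filtered [Image2D-class].
#' @export
medianFilter2D <- function(image, radius) {
  stopifnot(is(image, "Image2D"))
  checkCount(radius, "radius")
  if (radius == 0) return(image)
  m <- image@pixels
  h <- nrow(m); w <- ncol(m)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  iy <- reflectIndex(h, radius)
  ix <- reflectIndex(w, radius)
  pad <- m[iy, ix]
  stackm <- matrix(0, h * w, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    stackm[, k] <- pad[radius + offs$dy[k] + seq_len(h),
                       radius + offs$dx[k] + seq_len(w)]
  }
  med <- apply(stackm, 1L, median)
  Image2D(matrix(med, h, w), pixelSize = image@pixelSize)
}

#' Write a tri-level mask to an 8-bit image file
#'
#' The mask must contain only \{0, 128, 255\}; any other value is an error.
#' PNG or TIFF is chosen by file extension; roundtrip through
#' [readTrilevelMask()] is lossless.
#'
#' @param mask a [TriLevelMask-class] (or a plain matrix over \{0,128,255\}).
#' @param path output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
writeTrilevelMask <- function(mask, path) {
  px <- if (is(mask, "TriLevelMask")) mask@pixels else mask
  bad <- setdiff(unique(as.vector(px)), c(0, 128, 255))
  if (length(bad))
    stop("tri-level mask may only contain {0, 128, 255}; found ",
         paste(bad[seq_len(min(3, length(bad)))], collapse = ", "))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
  } else stop("unsupported mask format: .", ext, " (use .png or .tif)")
  invisible(path)
}

#' Read a tri-level mask
#'
#' @param path an 8-bit PNG or TIFF written by [writeTrilevelMask()].
#' @param pixelSize numeric(2), (dy, dx) in micrometres.
#' @return A [TriLevelMask-class].
#' @export
readTrilevelMask <- function(path, pixelSize = c(1, 1)) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(px)) > 2L) stop("tri-level mask must be single channel")
  px <- round(px * 255)
  bad <- setdiff(unique(as.vector(px)), c(0, 128, 255))
  if (length(bad)) stop("file is not a tri-level mask: found value ", bad[1])
  TriLevelMask(px, pixelSize = pixelSize)
}

#' Write / read a 16-bit label image
#'
#' Label images (nucleus or chromocenter labels) are stored as 16-bit
#' grayscale TIFFs with the label id as pixel value.
#'
#' @param labels integer matrix, 0 = background.
#' @param path output path (.tif).
#' @return `path` invisibly (write); an integer matrix (read).
#' @export
writeLabelImage <- function(labels, path) {
  if (max(labels) > 65535) stop("too many labels for 16-bit storage")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelImage
#' @export
readLabelImage <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) > 2L) stop("label image must be single channel")
  matrix(as.integer(m), nrow(m))
}
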