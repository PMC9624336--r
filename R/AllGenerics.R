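#' @rdname ZStack-class
#' @param object,x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname ZStack-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname ZStack-class
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname Image2D-class
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname Image2D-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname RoiSet-class
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @rdname RoiSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname RoiSet-class
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))
#' @rdname HeatmapPrediction-class
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname ZStack-class
#' @export
setMethod("voxels", "ZStack", function(x) x@voxels)
#' @rdname ZStack-class
#' @export
setMethod("voxelSize", "ZStack", function(x) x@voxelSize)
#' @rdname ZStack-class
#' @export
setMethod("bitDepth", "ZStack", function(x) x@bitDepth)
#' @rdname Image2D-class
#' @export
setMethod("pixels", "Image2D", function(x) x@pixels)
#' @rdname Image2D-class
#' @export
setMethod("pixelSize", "Image2D", function(x) x@pixelSize)
#' @rdname TriLevelMask-class
#' @export
setMethod("pixels", "TriLevelMask", function(x) x@pixels)
#' @rdname TriLevelMask-class
#' @export
setMethod("pixelSize", "TriLevelMask", function(x) x@pixelSize)
#' @rdname RoiSet-class
#' @export
setMethod("labelImage", "RoiSet", function(x) x@labelImage)
#' @rdname RoiSet-class
#' @export
setMethod("provenance", "RoiSet", function(x) x@provenance)
#' @rdname RoiSet-class
#' @export
setMethod("nLabels", "RoiSet", function(x) length(x@provenance))
#' @rdname HeatmapPrediction-class
#' @export
setMethod("probs", "HeatmapPrediction", function(x) x@probs)

setMethod("show", "ZStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ZStack: %d slices of %d x %d, %d-bit\n",
              d[1], d[2], d[3], object@bitDepth))
  cat(sprintf("  voxel size (dz, dy, dx): %.3g x %.3g x %.3g um\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Image2D: %d x %d, pixel size %.3g x %.3g um, range [%.4g, %.4g]\n",
              d[1], d[2], object@pixelSize[1], object@pixelSize[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "TriLevelMask", function(object) {
  p <- object@pixels
  cat(sprintf(
    "TriLevelMask: %d x %d (background %d px, nucleus %d px, chromocenter %d px)\n",
    nrow(p), ncol(p), sum(p == 0), sum(p == 128), sum(p == 255)))
})

setMethod("show", "RoiSet", function(object) {
  n <- length(object@provenance)
  cat(sprintf("RoiSet: %d nuclei on a %d x %d projection (min area %g px)\n",
              n, nrow(object@labelImage), ncol(object@labelImage),
              object@minArea))
  if (n > 0) {
    tab <- table(factor(object@provenance, levels = c("auto", "added")))
    cat(sprintf("  provenance: %d auto, %d added\n", tab["auto"], tab["added"]))
  }
})

setMethod("show", "HeatmapPrediction", function(object) {
  cat(sprintf("HeatmapPrediction: %d x %d, threshold %.3g, prob range [%.3g, %.3g]\n",
              nrow(object@probs), ncol(object@probs), object@threshold,
              min(object@probs), max(object@probs)))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig (%s): %d nuclei, field %d x %d, %d slices, seed %d\n",
              object@phenotype, object@nNuclei, object@fieldSize[1],
              object@fieldSize[2], object@nSlices, object@seed))
  cat(sprintf("  cc count %d-%d, contrast %.2f, noise (sd %.2g, poisson %.2g)\n",
              object@ccCountRange[1], object@ccCountRange[2],
              object@ccContrast, object@noise[1], object@noise[2]))
})

setMethod("show", "UNetConfig", function(object) {
  cat(sprintf("UNetConfig: depth %d, %d base filters, input %d x %d, loss %s\n",
              object@depth, object@baseFilters, object@inputSize[1],
              object@inputSize[2], object@loss))
  cat(sprintf("  %d epochs, batch %d, lr %.2g, seed %d\n", object@epochs,
              object@batchSize, object@learningRate, object@seed))
})
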