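#' @import methods
#' @importFrom stats median rnorm rpois runif sd quantile setNames cor
#' @importFrom utils write.csv read.csv modifyList
NULL

#' ZStack: a single-channel confocal z-stack
#'
#' Container for a 3D fluorescence intensity volume as acquired by confocal
#' z-stack imaging. Axis order is (z, y, x), 0 is background-dark, and all
#' intensities are non-negative. Voxel size is carried in micrometres as
#' (dz, dy, dx); when unknown it defaults to (1, 1, 1) so downstream areas
#' fall back to pixel units.
#'
#' @slot voxels 3D numeric array of non-negative intensities, dim (z, y, x).
#' @slot voxelSize numeric(3), (dz, dy, dx) in micrometres, all > 0.
#' @slot bitDepth integer, 8 or 16; the acquisition bit depth.
#'
#' @seealso [readZStack()], [zProject()], [cropNucleus()]
#' @export
setClass("ZStack",
  representation(voxels = "array", voxelSize = "numeric", bitDepth = "integer"),
  prototype(voxelSize = c(1, 1, 1), bitDepth = 16L),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L) return("voxels must be a 3D array (z, y, x)")
    if (dim(v)[1] < 1L) return("at least one z slice required")
    if (anyNA(v) || any(!is.finite(v))) return("voxels must be finite")
    if (any(v < 0)) return("intensities must be non-negative")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be three positive values (dz, dy, dx)")
    if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
    TRUE
  })

#' Image2D: a 2D intensity image
#'
#' A projected or otherwise 2D single-channel image with its pixel size
#' (dy, dx) in micrometres. Produced by [zProject()] and consumed by the
#' segmentation operations.
#'
#' @slot pixels numeric matrix (y, x), finite values.
#' @slot pixelSize numeric(2), (dy, dx) in micrometres.
#' @export
setClass("Image2D",
  representation(pixels = "matrix", pixelSize = "numeric"),
  prototype(pixelSize = c(1, 1)),
  validity = function(object) {
    if (anyNA(object@pixels) || any(!is.finite(object@pixels)))
      return("pixels must be finite")
    if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
      return("pixelSize must be two positive values (dy, dx)")
    TRUE
  })

#' TriLevelMask: background / nucleus / chromocenter annotation
#'
#' The tri-level annotation format used throughout: 0 for background, 128
#' for nucleus interior, 255 for chromocenters. Chromocenter pixels always
#' lie inside a nucleus region.
#'
#' @slot pixels numeric matrix over exactly \{0, 128, 255\}.
#' @slot pixelSize numeric(2), (dy, dx) in micrometres.
#' @seealso [composeTrilevel()], [writeTrilevelMask()], [readTrilevelMask()]
#' @export
setClass("TriLevelMask",
  representation(pixels = "matrix", pixelSize = "numeric"),
  prototype(pixelSize = c(1, 1)),
  validity = function(object) {
    p <- object@pixels
    if (!all(p %in% c(0, 128, 255)))
      return("tri-level mask may only contain values {0, 128, 255}")
    if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
      return("pixelSize must be two positive values (dy, dx)")
    TRUE
  })

#' RoiSet: labeled nucleus regions on a 2D projection
#'
#' Nucleus regions as a label image: 0 is background, k > 0 is nucleus k.
#' Labels are consecutive positive integers; each region is 4-connected and
#' at least `minArea` pixels. Every label carries a provenance tag, "auto"
#' for detected regions and "added" for regions introduced by curation.
#'
#' @slot labelImage integer matrix (y, x).
#' @slot provenance character vector, one of "auto"/"added" per label.
#' @slot minArea numeric, minimum region area in pixels.
#' @seealso [detectNuclei()], [applyCuration()]
#' @export
setClass("RoiSet",
  representation(labelImage = "matrix", provenance = "character",
                 minArea = "numeric"),
  validity = function(object) {
    li <- object@labelImage
    labs <- sort(unique(li[li > 0]))
    n <- length(labs)
    if (n > 0 && !identical(as.integer(labs), seq_len(n)))
      return("labels must be consecutive positive integers 1..n")
    if (length(object@provenance) != n)
      return("provenance must have one tag per label")
    if (n > 0 && !all(object@provenance %in% c("auto", "added")))
      return("provenance tags must be 'auto' or 'added'")
    TRUE
  })

#' HWatershedParams: batch parameters for the hierarchical watershed
#'
#' Replaces the three interactive controls of the H-watershed plugin with
#' batch parameters: the seed dynamics threshold `h` (a maximum survives as
#' a seed iff its dynamics, peak minus highest saddle towards a higher peak,
#' is at least `h`), an absolute intensity floor, and a peak-flooding
#' percentage truncating each region to pixels above
#' (1 - peakFlooding/100) * its peak value.
#'
#' @slot h numeric >= 0; dynamics threshold, in intensity units of the
#'   feature image, or as a fraction of the per-nucleus feature range when
#'   `hRelative` is TRUE.
#' @slot hRelative logical; interpret `h` relative to the feature range.
#' @slot intensityThreshold numeric; minimum pixel value kept in a region,
#'   absolute or (when `intensityRelative`) a fraction of the masked
#'   feature range above its minimum.
#' @slot intensityRelative logical; interpret the floor relative to the
#'   feature range.
#' @slot peakFlooding numeric in (0, 100]; percent of each peak flooded.
#' @export
setClass("HWatershedParams",
  representation(h = "numeric", hRelative = "logical",
                 intensityThreshold = "numeric",
                 intensityRelative = "logical", peakFlooding = "numeric"),
  prototype(h = 0.05, hRelative = TRUE, intensityThreshold = 0.25,
            intensityRelative = TRUE, peakFlooding = 30),
  validity = function(object) {
    if (object@h < 0) return("h must be >= 0")
    if (object@peakFlooding <= 0 || object@peakFlooding > 100)
      return("peakFlooding must lie in (0, 100]")
    TRUE
  })

#' HeatmapPrediction: per-pixel object probability
#'
#' The uncertainty heatmap emitted by a segmentation network: a per-pixel
#' probability in [0, 1] that the pixel belongs to the target object,
#' together with the threshold used to binarize it (0.5 by default, so a
#' pixel is kept as soon as object is more likely than background).
#'
#' @slot probs numeric matrix in [0, 1].
#' @slot threshold numeric in [0, 1], default 0.5.
#' @seealso [binarizeHeatmap()], [predictHeatmap()]
#' @export
setClass("HeatmapPrediction",
  representation(probs = "matrix", threshold = "numeric"),
  prototype(threshold = 0.5),
  validity = function(object) {
    if (any(object@probs < 0) || any(object@probs > 1))
      return("probabilities must lie in [0, 1]")
    if (object@threshold < 0 || object@threshold > 1)
      return("threshold must lie in [0, 1]")
    TRUE
  })

#' UNetConfig: architecture and training configuration for one U-Net stage
#'
#' @slot depth integer, number of pooling levels; input size must be
#'   divisible by 2^depth.
#' @slot baseFilters integer, filters in the first encoder level (doubling
#'   per level).
#' @slot inputSize integer(2), (H, W) of network input tiles.
#' @slot loss character, "bce", "dice" or "bcedice" (sum of both).
#' @slot epochs integer, training epochs.
#' @slot batchSize integer, minibatch size.
#' @slot learningRate numeric, Adam step size.
#' @slot seed integer, seed for initialization and shuffling.
#' @export
setClass("UNetConfig",
  representation(depth = "integer", baseFilters = "integer",
                 inputSize = "integer", loss = "character",
                 epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", seed = "integer"),
  prototype(depth = 2L, baseFilters = 8L, inputSize = c(64L, 64L),
            loss = "bcedice", epochs = 10L, batchSize = 4L,
            learningRate = 2e-3, seed = 1L),
  validity = function(object) {
    if (object@depth < 1L || object@baseFilters < 1L ||
        object@epochs < 1L || object@batchSize < 1L)
      return("counts must be positive")
    if (length(object@inputSize) != 2L || any(object@inputSize < 4L))
      return("inputSize must be (H, W), both >= 4")
    if (any(object@inputSize %% (2L^object@depth) != 0L))
      return("input size must be divisible by 2^depth")
    if (!object@loss %in% c("bce", "dice", "bcedice"))
      return("loss must be one of 'bce', 'dice', 'bcedice'")
    if (object@learningRate <= 0) return("learningRate must be positive")
    TRUE
  })

#' SceneConfig: parameters of the synthetic DAPI scene generator
#'
#' Describes one simulated field of view of DAPI-stained interphase nuclei:
#' elliptical nuclei with smooth nucleoplasm texture containing bright
#' chromocenter foci, optional touching nucleus pairs and non-nucleus
#' debris, rendered as a z-stack with Gaussian and Poisson noise. Presets
#' emulate the qualitative phenotypes of light-grown (8-10 conspicuous
#' high-contrast foci), dark-grown (fewer, fainter foci in larger nuclei)
#' and ddm1-like (small, faint, dispersed foci) material.
#'
#' @slot nNuclei integer, nuclei per field.
#' @slot nucleusRadiusRange numeric(2), semi-axis range in pixels.
#' @slot ccCountRange integer(2), chromocenters per nucleus.
#' @slot ccRadiusRange numeric(2), chromocenter radius range in pixels.
#' @slot ccContrast numeric > 1 for conspicuous foci; ratio of chromocenter
#'   mean to nucleoplasm mean intensity.
#' @slot targetRhfRange numeric(2); the RHF range the preset is expected to
#'   produce (informative, recorded in manifests; not a control knob).
#' @slot noise numeric(2), (gaussianSd, poissonScale); poissonScale 0
#'   disables shot noise, 1 applies Poisson resampling of intensities.
#' @slot nSlices integer, z slices.
#' @slot fieldSize integer(2), (H, W) of the field in pixels.
#' @slot touchingProb numeric in [0, 1], probability a nucleus is placed
#'   touching the previous one.
#' @slot debrisProb numeric in [0, 1], probability of each of up to 3 small
#'   extra-nuclear debris blobs.
#' @slot phenotype character, one of "light", "dark", "ddm1", "custom".
#' @slot seed integer RNG seed; the same config is bit-reproducible.
#' @seealso [sceneConfig()], [generateScene()]
#' @export
setClass("SceneConfig",
  representation(nNuclei = "integer", nucleusRadiusRange = "numeric",
                 ccCountRange = "integer", ccRadiusRange = "numeric",
                 ccContrast = "numeric", targetRhfRange = "numeric",
                 noise = "numeric", nSlices = "integer",
                 fieldSize = "integer", touchingProb = "numeric",
                 debrisProb = "numeric", phenotype = "character",
                 seed = "integer"),
  validity = function(object) {
    rng <- function(r) length(r) == 2L && r[1] <= r[2]
    if (object@nNuclei < 1L) return("nNuclei must be >= 1")
    if (!rng(object@nucleusRadiusRange) || object@nucleusRadiusRange[1] <= 0)
      return("nucleusRadiusRange must be a well-ordered positive range")
    if (!rng(object@ccCountRange) || object@ccCountRange[1] < 0L)
      return("ccCountRange must be a well-ordered non-negative range")
    if (!rng(object@ccRadiusRange) || object@ccRadiusRange[1] <= 0)
      return("ccRadiusRange must be a well-ordered positive range")
    if (object@ccContrast <= 0) return("ccContrast must be positive")
    if (object@phenotype == "light" && object@ccContrast <= 1)
      return("light preset requires ccContrast > 1")
    if (length(object@noise) != 2L || any(object@noise < 0))
      return("noise must be (gaussianSd, poissonScale), both >= 0")
    if (object@touchingProb < 0 || object@touchingProb > 1 ||
        object@debrisProb < 0 || object@debrisProb > 1)
      return("probabilities must lie in [0, 1]")
    if (!object@phenotype %in% c("light", "dark", "ddm1", "custom"))
      return("phenotype must be light, dark, ddm1 or custom")
    if (object@nSlices < 1L) return("nSlices must be >= 1")
    TRUE
  })

#' GroundTruth: exact annotation accompanying a synthetic scene
#'
#' Ground truth is computed on the noiseless rendering, before Gaussian and
#' Poisson noise are added, so morphometric records are exact oracles.
#'
#' @slot trilevel [TriLevelMask-class] annotation of the field.
#' @slot nucleusLabels integer matrix, per-nucleus label image.
#' @slot ccLabels integer matrix, per-chromocenter label image.
#' @slot records data.frame of per-nucleus morphometrics (see
#'   [measureBatch()]) measured on the noiseless projection.
#' @slot rafs list of per-nucleus numeric vectors of per-chromocenter
#'   area fractions.
#' @slot nucleusCentroids numeric matrix (n, 2), (y, x) centroids.
#' @slot ccCentroids numeric matrix (m, 2), (y, x) chromocenter centroids.
#' @export
setClass("GroundTruth",
  representation(trilevel = "TriLevelMask", nucleusLabels = "matrix",
                 ccLabels = "matrix", records = "data.frame",
                 rafs = "list", nucleusCentroids = "matrix",
                 ccCentroids = "matrix"))
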