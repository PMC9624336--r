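#' Build a SceneConfig, optionally from a phenotype preset
#'
#' Presets encode the qualitative phenotypes the generator emulates:
#' \describe{
#'   \item{light}{8-10 conspicuous, high-contrast chromocenter foci per
#'     nucleus (contrast 2.2).}
#'   \item{dark}{fewer (4-8), fainter (contrast 1.4) foci in larger nuclei,
#'     emulating heterochromatin relaxation of dark-grown material.}
#'   \item{ddm1}{4-8 small, faint (contrast 1.6) dispersed foci in smaller
#'     nuclei.}
#' }
#' Exact values are generator parameters, chosen once as realistic defaults
#' for DAPI-stained Arabidopsis cotyledon/leaf nuclei; any can be
#' overridden.
#'
#' @param phenotype "light", "dark", "ddm1" or "custom".
#' @param seed RNG seed; the same config renders bit-identically.
#' @param ... overrides of any [SceneConfig-class] slot.
#' @return A [SceneConfig-class].
#' @export
sceneConfig <- function(phenotype = c("light", "dark", "ddm1", "custom"),
                        seed = 1L, ...) {
  phenotype <- match.arg(phenotype)
  base <- switch(phenotype,
    light = list(nNuclei = 3L, nucleusRadiusRange = c(18, 24),
                 ccCountRange = c(8L, 10L), ccRadiusRange = c(1.6, 2.4),
                 ccContrast = 2.2, targetRhfRange = c(0.12, 0.22)),
    dark = list(nNuclei = 3L, nucleusRadiusRange = c(22, 28),
                ccCountRange = c(4L, 8L), ccRadiusRange = c(1.4, 2.2),
                ccContrast = 1.4, targetRhfRange = c(0.02, 0.10)),
    ddm1 = list(nNuclei = 3L, nucleusRadiusRange = c(15, 20),
                ccCountRange = c(4L, 8L), ccRadiusRange = c(1.0, 1.8),
                ccContrast = 1.6, targetRhfRange = c(0.02, 0.12)),
    custom = list(nNuclei = 3L, nucleusRadiusRange = c(18, 24),
                  ccCountRange = c(4L, 8L), ccRadiusRange = c(1.4, 2.2),
                  ccContrast = 1.8, targetRhfRange = c(0, 1)))
  args <- utils::modifyList(c(base, list(
    noise = c(3, 1), nSlices = 7L, fieldSize = c(192L, 192L),
    touchingProb = 0.15, debrisProb = 0.3,
    phenotype = phenotype, seed = as.integer(seed))), list(...))
  args$nNuclei <- as.integer(args$nNuclei)
  args$ccCountRange <- as.integer(args$ccCountRange)
  args$nSlices <- as.integer(args$nSlices)
  args$fieldSize <- as.integer(args$fieldSize)
  args$seed <- as.integer(args$seed)
  do.call(new, c(list("SceneConfig"), args))
}

## sample nucleus geometries (centers, semi-axes, orientation) with
## rejection so non-touching nuclei stay separated
sampleNucleusGeometry <- function(cfg) {
  H <- cfg@fieldSize[1]; W <- cfg@fieldSize[2]
  nuc <- list()
  maxTries <- 400L
  for (k in seq_len(cfg@nNuclei)) {
    a <- runif(1, cfg@nucleusRadiusRange[1], cfg@nucleusRadiusRange[2])
    b <- a * runif(1, 0.75, 0.95)
    th <- runif(1, 0, pi)
    touch <- k > 1L && runif(1) < cfg@touchingProb
    placed <- FALSE
    for (t in seq_len(maxTries)) {
      if (touch) {
        prev <- nuc[[k - 1L]]
        ang <- runif(1, 0, 2 * pi)
        dist <- (prev$a + a) * 0.92
        cy <- prev$cy + dist * sin(ang); cx <- prev$cx + dist * cos(ang)
      } else {
        cy <- runif(1, a + 2, H - a - 2); cx <- runif(1, a + 2, W - a - 2)
      }
      if (cy < a * 0.6 || cy > H - a * 0.6 ||
          cx < a * 0.6 || cx > W - a * 0.6) next
      ok <- TRUE
      for (j in seq_len(k - 1L)) {
        dd <- sqrt((cy - nuc[[j]]$cy)^2 + (cx - nuc[[j]]$cx)^2)
        lim <- if (touch && j == k - 1L) (nuc[[j]]$a + a) * 0.85
               else nuc[[j]]$a + a + 4
        if (dd < lim) { ok <- FALSE; break }
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed)
      stop("infeasible geometry: could not place ", cfg@nNuclei,
           " nuclei of this size in a ", H, " x ", W, " field")
    nuc[[k]] <- list(cy = cy, cx = cx, a = a, b = b, th = th)
  }
  nuc
}

## elliptical distance field (<= 1 inside) for one nucleus over the grid
ellipseField <- function(nucGeom, H, W) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- yy - nucGeom$cy; dx <- xx - nucGeom$cx
  u <- dx * cos(nucGeom$th) + dy * sin(nucGeom$th)
  v <- -dx * sin(nucGeom$th) + dy * cos(nucGeom$th)
  sqrt((u / nucGeom$a)^2 + (v / nucGeom$b)^2)
}

#' Generate one synthetic DAPI scene with exact ground truth
#'
#' Renders elliptical nuclei with a smooth nucleoplasm texture and bright
#' 3D-Gaussian chromocenter foci at the configured contrast, optional
#' touching nucleus pairs and small extranuclear debris, as a z-stack.
#' Ground truth (tri-level mask, label images, per-nucleus morphometrics)
#' is computed on the noiseless rendering; Gaussian and Poisson noise are
#' added last. Identical configs render bit-identically.
#'
#' @param config a [SceneConfig-class].
#' @return A list: `stack` (noisy [ZStack-class]), `noiseless` (noise-free
#'   [ZStack-class]) and `truth` ([GroundTruth-class]).
#' @export
generateScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  set.seed(config@seed)
  H <- config@fieldSize[1]; W <- config@fieldSize[2]
  nz <- config@nSlices
  bg <- 12; nucLevel <- 70
  nuc <- sampleNucleusGeometry(config)
  n <- length(nuc)

  ## nucleus footprints; contested pixels go to the nearest center
  fields <- lapply(nuc, ellipseField, H = H, W = W)
  nucLab <- matrix(0L, H, W)
  bestD <- matrix(Inf, H, W)
  for (k in seq_len(n)) {
    inside <- fields[[k]] <= 1
    closer <- inside & (fields[[k]] < bestD)
    nucLab[closer] <- k
    bestD[closer] <- fields[[k]][closer]
  }

  ## smooth nucleoplasm texture (low-frequency multiplicative field)
  tex <- convolve2dSep(matrix(rnorm(H * W), H, W), gaussKernel1d(6))
  tex <- 1 + 0.08 * tex / max(1e-9, sd(tex))

  ## chromocenter placement: non-overlapping disks inside each nucleus
  gy <- matrix(seq_len(H), H, W)
  gx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ccLab <- matrix(0L, H, W)
  ccCenters <- NULL
  ccList <- list()
  ccId <- 0L
  for (k in seq_len(n)) {
    g <- nuc[[k]]
    nCC <- if (config@ccCountRange[2] == 0L) 0L else
      sample(config@ccCountRange[1]:config@ccCountRange[2], 1)
    placedCC <- list()
    for (q in seq_len(nCC)) {
      for (t in seq_len(200L)) {
        r <- runif(1, config@ccRadiusRange[1], config@ccRadiusRange[2])
        rho <- sqrt(runif(1)) * 0.75
        ang <- runif(1, 0, 2 * pi)
        u <- rho * g$a * cos(ang); v <- rho * g$b * sin(ang)
        cy <- g$cy + u * sin(g$th) + v * cos(g$th)
        cx <- g$cx + u * cos(g$th) - v * sin(g$th)
        ok <- TRUE
        for (pc in placedCC)
          if (sqrt((cy - pc$cy)^2 + (cx - pc$cx)^2) < pc$r + r + 1.5) {
            ok <- FALSE; break
          }
        if (!ok) next
        ## disk must stay inside this nucleus's own pixels
        y0 <- max(1L, floor(cy - r - 1)); y1 <- min(H, ceiling(cy + r + 1))
        x0 <- max(1L, floor(cx - r - 1)); x1 <- min(W, ceiling(cx + r + 1))
        yy <- matrix(y0:y1, y1 - y0 + 1L, x1 - x0 + 1L)
        xx <- matrix(x0:x1, y1 - y0 + 1L, x1 - x0 + 1L, byrow = TRUE)
        disk <- (yy - cy)^2 + (xx - cx)^2 <= r^2
        if (!any(disk)) next
        if (!all(nucLab[y0:y1, x0:x1][disk] == k)) next
        ccId <- ccId + 1L
        sub <- ccLab[y0:y1, x0:x1]; sub[disk] <- ccId
        ccLab[y0:y1, x0:x1] <- sub
        placedCC[[length(placedCC) + 1L]] <- list(cy = cy, cx = cx, r = r)
        ccList[[ccId]] <- list(cy = cy, cx = cx, r = r, nucleus = k)
        ccCenters <- rbind(ccCenters, c(cy, cx))
        break
      }
    }
  }

  ## render the stack: nucleoplasm with z profile, chromocenter bumps,
  ## debris blobs outside nuclei
  zc <- (nz + 1) / 2
  sigZ <- max(1, nz / 3.2)
  zProf <- 0.35 + 0.65 * exp(-((seq_len(nz) - zc)^2) / (2 * sigZ^2))
  base2d <- matrix(0, H, W)
  for (k in seq_len(n)) {
    inside <- nucLab == k
    edge <- pmin(pmax(1 - fields[[k]], 0) * 6, 1)  # soft rim falloff
    base2d[inside] <- nucLevel * tex[inside] * edge[inside]
  }
  ## chromocenter amplitude: disk-mean approximately contrast * nucleoplasm
  cc2d <- matrix(0, H, W)
  if (ccId > 0L) for (q in seq_len(ccId)) {
    b <- ccList[[q]]
    sig <- b$r / 1.6
    amp <- nucLevel * (config@ccContrast - 1) / 0.56
    y0 <- max(1L, floor(b$cy - 4 * sig)); y1 <- min(H, ceiling(b$cy + 4 * sig))
    x0 <- max(1L, floor(b$cx - 4 * sig)); x1 <- min(W, ceiling(b$cx + 4 * sig))
    yys <- matrix(y0:y1, y1 - y0 + 1L, x1 - x0 + 1L)
    xxs <- matrix(x0:x1, y1 - y0 + 1L, x1 - x0 + 1L, byrow = TRUE)
    bump <- amp * exp(-((yys - b$cy)^2 + (xxs - b$cx)^2) / (2 * sig^2))
    keep <- nucLab[y0:y1, x0:x1] == b$nucleus
    cc2d[y0:y1, x0:x1][keep] <- cc2d[y0:y1, x0:x1][keep] + bump[keep]
  }
  ## debris outside nuclei (small bright contaminants, below any plausible
  ## nucleus area, exercising curation and min-area filtering downstream)
  debris2d <- matrix(0, H, W)
  for (q in seq_len(3L)) {
    if (runif(1) >= config@debrisProb) next
    for (t in seq_len(100L)) {
      r <- runif(1, 2, 5)
      cy <- runif(1, r + 4, H - r - 4); cx <- runif(1, r + 4, W - r - 4)
      y0 <- max(1L, floor(cy - r - 4)); y1 <- min(H, ceiling(cy + r + 4))
      x0 <- max(1L, floor(cx - r - 4)); x1 <- min(W, ceiling(cx + r + 4))
      if (any(nucLab[y0:y1, x0:x1] > 0)) next
      dd <- (gy - cy)^2 + (gx - cx)^2
      debris2d <- debris2d + nucLevel * 0.9 * exp(-dd / (2 * (r / 1.5)^2))
      break
    }
  }

  ccSigZ <- 1.4  # axial extent of chromocenter foci, in slices
  clean <- array(0, c(nz, H, W))
  for (z in seq_len(nz)) {
    ccz <- cc2d * exp(-((z - zc)^2) / (2 * ccSigZ^2))
    clean[z, , ] <- bg + base2d * zProf[z] + ccz + debris2d * zProf[z]
  }
  clean <- round(pmax(clean, 0))

  ## ground truth on the noiseless rendering; voxel size mirrors typical
  ## confocal acquisition (0.35 um slice spacing, 0.1 um pixels)
  vs <- c(0.35, 0.1, 0.1)
  noiseless <- ZStack(clean, voxelSize = vs, bitDepth = 16L)
  cleanProj <- zProject(noiseless, "max")
  trilevel <- composeTrilevel(nucLab > 0L, ccLab, pixelSize = vs[2:3])
  meas <- measureBatch(nucLab, ccLab, cleanProj, pixelSize = vs[2:3])
  rafs <- split(meas$raf$raf, factor(meas$raf$nucleus_id, levels = seq_len(n)))
  truth <- new("GroundTruth", trilevel = trilevel, nucleusLabels = nucLab,
               ccLabels = ccLab, records = meas$records,
               rafs = unname(rafs),
               nucleusCentroids = labelCentroids(nucLab),
               ccCentroids = if (is.null(ccCenters))
                 matrix(numeric(0), 0, 2) else ccCenters)

  ## noise last: Poisson shot noise then additive Gaussian read noise
  noisy <- clean
  if (config@noise[2] > 0) {
    lam <- noisy * config@noise[2]
    noisy <- array(rpois(length(lam), lam) / config@noise[2], dim(lam))
  }
  if (config@noise[1] > 0)
    noisy <- noisy + rnorm(length(noisy), sd = config@noise[1])
  noisy <- round(pmax(noisy, 0))
  list(stack = ZStack(noisy, voxelSize = vs, bitDepth = 16L),
       noiseless = noiseless, truth = truth)
}

#' Write a set of synthetic scenes to disk
#'
#' Scene i uses seed `config@seed + i - 1`. Files are
#' `<prefix>_<i>.tif` (stack), `<prefix>_<i>_mask.png` (tri-level mask) and
#' a `manifest.csv` of per-nucleus ground-truth morphometrics.
#'
#' @param config a [SceneConfig-class] (its seed is the base seed).
#' @param nScenes number of scenes (>= 1).
#' @param outDir output directory, created if needed.
#' @param prefix file name prefix, default "scene".
#' @return The manifest data.frame, invisibly.
#' @export
generateTrainingSet <- function(config, nScenes, outDir, prefix = "scene") {
  stopifnot(nScenes >= 1)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  rows <- vector("list", nScenes)
  for (i in seq_len(nScenes)) {
    cfg <- config
    cfg@seed <- config@seed + i - 1L
    sc <- generateScene(cfg)
    name <- sprintf("%s_%03d", prefix, i)
    writeZStack(sc$stack, file.path(outDir, paste0(name, ".tif")))
    writeTrilevelMask(sc$truth@trilevel,
                      file.path(outDir, paste0(name, "_mask.png")))
    rec <- sc$truth@records
    rec$image <- name
    rec$seed <- cfg@seed
    rows[[i]] <- rec
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
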