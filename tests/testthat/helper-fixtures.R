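# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code under fixed seeds; no data files.

# binary disk mask / disk image
diskMask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

diskImage <- function(h, w, centers, r, fg = 200, bg = 10) {
  m <- matrix(bg, h, w)
  for (i in seq_len(nrow(centers)))
    m[diskMask(h, w, centers[i, 1], centers[i, 2], r)] <- fg
  m
}

# two-Gaussian-peak image; peak 1 is the higher one
twoPeakImage <- function(h = 48, w = 48, c1 = c(14, 24), c2 = c(34, 24),
                         a1 = 10, a2 = 6, sigma2 = 18) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  a1 * exp(-((yy - c1[1])^2 + (xx - c1[2])^2) / sigma2) +
    a2 * exp(-((yy - c2[1])^2 + (xx - c2[2])^2) / sigma2)
}

# brute-force dynamics of the secondary maximum of a discrete image:
# highest threshold at which the two given peak pixels are 4-connected,
# scanned over all distinct image levels; dynamics = lower peak - saddle
peakDynamicsOracle <- function(img, p1, p2) {
  v1 <- img[p1[1], p1[2]]; v2 <- img[p2[1], p2[2]]
  lower <- min(v1, v2)
  levels <- sort(unique(as.vector(img)), decreasing = TRUE)
  for (t in levels) {
    lab <- floodLabel4(img >= t)
    if (lab[p1[1], p1[2]] > 0 && lab[p1[1], p1[2]] == lab[p2[1], p2[2]])
      return(lower - t)
  }
  lower - min(img)
}

# independent 4-connected labeling by iterative minimum propagation
floodLabel4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    old <- lab
    up <- rbind(lab[-1, , drop = FALSE], 0L)
    dn <- rbind(0L, lab[-h, , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], 0L)
    rt <- cbind(0L, lab[, -w, drop = FALSE])
    for (nb in list(up, dn, lf, rt)) {
      both <- mask & nb > 0L
      lab[both] <- pmin(lab[both], nb[both])
    }
    if (identical(lab, old)) break
  }
  lab
}

# direct (definitional) minimum cross-entropy objective: sum over pixels of
# g * log(g / mu_class), zero-intensity pixels contributing zero
crossEntropyObjective <- function(g, t) {
  lowSel <- g <= t
  muL <- mean(g[lowSel]); muH <- mean(g[!lowSel])
  term <- function(gg, mu) {
    gg <- gg[gg > 0]
    if (!length(gg) || mu <= 0) return(0)
    sum(gg * log(gg / mu))
  }
  term(g[lowSel], muL) + term(g[!lowSel], muH)
}

mceOracle <- function(img) {
  g <- as.vector(img)
  vals <- sort(unique(g))
  cand <- vals[-length(vals)]
  obj <- vapply(cand, function(t) crossEntropyObjective(g, t), numeric(1))
  cand[which.min(obj)]
}

# a random nucleus fixture: one blobby nucleus mask, a few cc disks inside,
# strictly positive random intensities
randomNucleusFixture <- function(h = 40, w = 40) {
  cy <- runif(1, 15, 25); cx <- runif(1, 15, 25)
  r <- runif(1, 9, 13)
  nuc <- diskMask(h, w, cy, cx, r)
  nCC <- sample(0:4, 1)
  cc <- matrix(0L, h, w)
  for (k in seq_len(nCC)) {
    ang <- runif(1, 0, 2 * pi); rho <- runif(1, 0, r - 3.5)
    d <- diskMask(h, w, cy + rho * sin(ang), cx + rho * cos(ang),
                  runif(1, 1.2, 2.5)) & nuc & cc == 0L
    cc[d] <- k
  }
  img <- matrix(runif(h * w, 5, 50), h, w)
  img[cc > 0L] <- img[cc > 0L] * runif(1, 1.5, 3)
  list(nucleus = nuc, cc = chromoseg:::relabelConsecutive(cc), intensity = img)
}

# desk-scale fragment set from generator scenes (mixed phenotypes);
# returns list of fragments with trueHF attached
deskFragments <- function(seeds, size = c(64L, 64L)) {
  presets <- rep(c("light", "dark", "ddm1"), length.out = length(seeds))
  out <- list()
  for (i in seq_along(seeds)) {
    sc <- generateScene(sceneConfig(presets[i], seed = seeds[i]))
    proj <- pixels(zProject(sc$stack, "max"))
    fr <- extractFragments(proj, sc$truth@nucleusLabels, sc$truth@ccLabels,
                           size = size, marginFrac = 0.15)
    for (k in seq_along(fr)) fr[[k]]$trueHF <- sc$truth@records$hf[k]
    out <- c(out, fr)
  }
  out
}

deskUNetConfig <- function(seed = 1L, epochs = 10L) {
  uNetConfig(depth = 2L, baseFilters = 8L, inputSize = c(64L, 64L),
             epochs = epochs, batchSize = 4L, learningRate = 2e-3,
             seed = as.integer(seed))
}
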