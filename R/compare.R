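#' Dice coefficient between two binary masks
#'
#' 2|A intersect B| / (|A| + |B|). A coefficient of 1 means the masks are
#' identical; two empty masks are defined to agree perfectly (dice 1).
#'
#' @param maskA,maskB logical (or 0/1) matrices of the same shape.
#' @return The Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(maskA, maskB) {
  a <- maskA > 0; b <- maskB > 0
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Match objects between two label images and score per-object Dice
#'
#' Objects are paired greedily by descending pixel overlap, each label used
#' at most once (ties broken by the smaller label pair for determinism);
#' per-pair Dice is computed on the two object masks. Objects left without
#' a partner are reported with dice 0.
#'
#' @param labelsA,labelsB integer label matrices of the same shape.
#' @return A data.frame with columns `label_a`, `label_b` (NA when
#'   unmatched), `overlap_px` and `dice`, ordered matched pairs first.
#' @export
matchObjects <- function(labelsA, labelsB) {
  if (!all(dim(labelsA) == dim(labelsB))) stop("label image shapes differ")
  areaA <- tabulate(labelsA[labelsA > 0L])
  areaB <- tabulate(labelsB[labelsB > 0L])
  both <- labelsA > 0L & labelsB > 0L
  if (any(both)) {
    ov <- as.data.frame(table(a = labelsA[both], b = labelsB[both]),
                        stringsAsFactors = FALSE)
    ov <- ov[ov$Freq > 0, ]
    ov$a <- as.integer(ov$a); ov$b <- as.integer(ov$b)
    ov <- ov[order(-ov$Freq, ov$a, ov$b), ]
  } else {
    ov <- data.frame(a = integer(0), b = integer(0), Freq = integer(0))
  }
  usedA <- logical(length(areaA)); usedB <- logical(length(areaB))
  rows <- list()
  for (i in seq_len(nrow(ov))) {
    a <- ov$a[i]; b <- ov$b[i]
    if (usedA[a] || usedB[b]) next
    usedA[a] <- TRUE; usedB[b] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      label_a = a, label_b = b, overlap_px = ov$Freq[i],
      dice = 2 * ov$Freq[i] / (areaA[a] + areaB[b]))
  }
  for (a in which(!usedA & areaA > 0))
    rows[[length(rows) + 1L]] <- data.frame(label_a = a, label_b = NA_integer_,
                                            overlap_px = 0L, dice = 0)
  for (b in which(!usedB & areaB > 0))
    rows[[length(rows) + 1L]] <- data.frame(label_a = NA_integer_, label_b = b,
                                            overlap_px = 0L, dice = 0)
  if (!length(rows))
    return(data.frame(label_a = integer(0), label_b = integer(0),
                      overlap_px = integer(0), dice = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two segmentations, whole-mask and per-object
#'
#' Convenience wrapper reporting the whole-mask Dice of the union
#' foregrounds together with the per-object matching of [matchObjects()].
#'
#' @param labelsA,labelsB integer label matrices of the same shape.
#' @return A list with `maskDice` and `objects` (the match table).
#' @export
compareSegmentations <- function(labelsA, labelsB) {
  list(maskDice = diceCoefficient(labelsA > 0L, labelsB > 0L),
       objects = matchObjects(labelsA, labelsB))
}
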