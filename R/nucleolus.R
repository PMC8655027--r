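## Nucleolar marker scoring (NPM1 / NCL).
## "Ring-like"/"circular" nucleolar signal is operationalized as: connected
## components of marker signal above a contrast threshold inside the
## nucleus, hole-filled, then filtered by area fraction and circularity.
## The ring score (rim vs core contrast of the largest candidate) is
## reported but does not enter the positive call.

#' Nucleolar scoring parameters
#'
#' @param contrastMin candidate threshold and acceptance contrast: candidate
#'   pixels/components must exceed `contrastMin` times the
#'   background-subtracted nucleoplasm estimate (per-nucleus median).
#' @param areaFractionRange accepted candidate area as a fraction of the
#'   nucleus area.
#' @param circularityMin minimum circularity `4*pi*A/P^2` of a candidate.
#' @param fillHoles fill candidate holes before measuring (turns an annulus
#'   into its full disk, matching the confocal reading of a circular
#'   nucleolar body).
#' @param minNucleusPx nuclei smaller than this are skipped with a flag.
#' @return Named parameter list for [scoreNucleolus()].
#' @export
nucleolusParams <- function(contrastMin = 1.5,
                            areaFractionRange = c(0.01, 0.30),
                            circularityMin = 0.6, fillHoles = TRUE,
                            minNucleusPx = 10L) {
  list(contrastMin = contrastMin, areaFractionRange = areaFractionRange,
       circularityMin = circularityMin, fillHoles = fillHoles,
       minNucleusPx = as.integer(minNucleusPx))
}

## rim-vs-core contrast of one component, on background-subtracted values:
## core = pixels deeper than half the maximum boundary distance
.ringScore <- function(img, compPix, shape, bg) {
  rows <- ((compPix - 1L) %% shape[1]) + 1L
  cols <- ((compPix - 1L) %/% shape[1]) + 1L
  r0 <- min(rows); c0 <- min(cols)
  m <- matrix(0L, max(rows) - r0 + 3L, max(cols) - c0 + 3L)
  m[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- 1L
  dm <- EBImage::imageData(EBImage::distmap(m))
  inside <- m == 1L
  core <- inside & dm >= 0.5 * max(dm)
  if (!any(core)) core <- inside & dm == max(dm)
  rim <- inside & !core
  if (!any(rim)) return(NA_real_)
  vals <- matrix(NA_real_, nrow(m), ncol(m))
  vals[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- img[compPix] - bg
  mr <- mean(vals[rim]); mc <- mean(vals[core])
  if (mr + mc == 0) return(NA_real_)
  (mr - mc) / (mr + mc)
}

#' Score nucleolar marker signal per nucleus
#'
#' Classifies every nucleus of a segmentation as carrying a compact
#' ("nucleolar") marker signal or a delocalized one, and measures the
#' summed nucleolar area, the rim-vs-core ring score of the largest
#' candidate, and the background-subtracted whole-nucleus mean intensity.
#' Marker channels are scored independently.
#'
#' @param field an [ImageField-class].
#' @param nuclei a [NucleusSet-class] from [segmentNuclei()].
#' @param marker `"NPM1"` or `"NCL"` (any channel name present works).
#' @param params parameters from [nucleolusParams()].
#' @return `data.frame`, one row per nucleus: `fieldId`, `nucleusId`,
#'   `marker`, `positive`, `nNucleoli`, `nucleolarAreaUm2` (0 when
#'   negative), `ringScore` (`NA` when negative), `nuclearMeanIntensity`,
#'   `skipped`. Degenerate nuclei (below `minNucleusPx`) are flagged
#'   `skipped` and excluded from aggregation.
#' @examples
#' sim <- simulateField(fieldSpec(nNuclei = 6, seed = 2))
#' ns <- segmentNuclei(sim$field)
#' head(scoreNucleolus(sim$field, ns, "NPM1"))
#' @export
scoreNucleolus <- function(field, nuclei, marker = c("NPM1", "NCL"),
                           params = nucleolusParams()) {
  marker <- marker[1]
  if (!marker %in% channelNames(field))
    stop("marker channel '", marker, "' not present in field")
  img <- getChannel(field, marker)
  lab <- labelMask(nuclei)
  tab <- nucleusTable(nuclei)
  pxs <- pixelSize(nuclei)
  sh <- dim(img)
  n <- nrow(tab)

  out <- data.frame(fieldId = rep_len(fieldId(nuclei), n),
                    nucleusId = tab$nucleusId, marker = rep_len(marker, n),
                    positive = rep_len(FALSE, n), nNucleoli = rep_len(0L, n),
                    nucleolarAreaUm2 = rep_len(0, n),
                    ringScore = rep_len(NA_real_, n),
                    nuclearMeanIntensity = rep_len(NA_real_, n),
                    skipped = rep_len(FALSE, n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  bg <- .modalIntensity(img)
  pix <- which(lab > 0L)
  lp <- lab[pix]
  val <- img[pix]
  areaPx <- tabulate(lp, nbins = n)
  npMed <- as.numeric(tapply(val, factor(lp, levels = seq_len(n)), stats::median))
  npSub <- pmax(npMed - bg, 1e-6)
  out$nuclearMeanIntensity <-
    rowsum(val, factor(lp, levels = seq_len(n)))[, 1] / areaPx - bg

  small <- areaPx < params$minNucleusPx
  if (any(small)) {
    out$skipped[small] <- TRUE
    message(sum(small), " nucleus/nuclei skipped in '", fieldId(nuclei),
            "': mask below ", params$minNucleusPx, " px")
  }

  cand <- matrix(FALSE, sh[1], sh[2])
  cand[pix] <- (val - bg) >= params$contrastMin * npSub[lp]
  if (!any(cand)) return(out)
  if (params$fillHoles) cand <- EBImage::imageData(EBImage::fillHull(cand)) > 0
  comp <- EBImage::bwlabel(cand)
  shape <- EBImage::computeFeatures.shape(comp)
  compData <- EBImage::imageData(comp)
  cpix <- which(compData > 0L)
  cl <- as.integer(compData[cpix])
  ncomp <- max(cl)
  compArea <- tabulate(cl, nbins = ncomp)
  compMean <- rowsum(img[cpix], factor(cl, levels = seq_len(ncomp)))[, 1] /
    compArea
  ## nucleus owning each component (majority vote over member pixels)
  labAt <- lab[cpix]
  compNuc <- vapply(split(labAt, cl), function(v) {
    v <- v[v > 0L]
    if (!length(v)) return(0L)
    as.integer(names(which.max(table(v))))
  }, integer(1))

  perim <- shape[, "s.perimeter"]
  circ <- 4 * pi * compArea / pmax(perim, 1)^2
  nucArea <- areaPx[pmax(compNuc, 1L)]
  areaFrac <- compArea / nucArea
  contrast <- (compMean - bg) / npSub[pmax(compNuc, 1L)]
  accepted <- compNuc > 0L & !small[pmax(compNuc, 1L)] &
    areaFrac >= params$areaFractionRange[1] &
    areaFrac <= params$areaFractionRange[2] &
    circ >= params$circularityMin & contrast >= params$contrastMin

  if (any(accepted)) {
    accIdx <- which(accepted)
    fl <- factor(compNuc[accIdx], levels = seq_len(n))
    out$nNucleoli <- as.integer(table(fl))
    out$positive <- out$nNucleoli > 0L
    areaSum <- as.numeric(tapply(compArea[accIdx], fl, sum))
    areaSum[is.na(areaSum)] <- 0
    out$nucleolarAreaUm2 <- areaSum * pxs^2
    ## ring score of the largest accepted candidate per positive nucleus
    for (i in which(out$positive)) {
      comps <- accIdx[compNuc[accIdx] == i]
      big <- comps[which.max(compArea[comps])]
      out$ringScore[i] <- .ringScore(img, cpix[cl == big], sh, bg)
    }
  }
  out
}

#' Per-sample fraction of nucleolar-positive nuclei
#'
#' Per-field fraction of positive nuclei, then mean over each sample's
#' fields (per-sample means are the statistical unit downstream).
#'
#' @param measurements output of [scoreNucleolus()] (rows from one or more
#'   fields, one marker).
#' @param manifest cohort manifest (see [cohortManifest()]); `NULL` gives
#'   per-field fractions.
#' @return See [summarizeBySample()]; `value` is a fraction in \[0, 1\].
#' @export
fractionPositive <- function(measurements, manifest = NULL) {
  summarizeBySample(measurements, "positive", manifest)
}

#' Per-sample mean nucleolar marker area per DAPI-positive nucleus
#'
#' By default every segmented nucleus counts in the denominator: negative
#' nuclei contribute an area of 0 (the readout is marker area per
#' DAPI-positive nucleus, not per marker-positive nucleus). Use
#' `over = "positives"` for the mean over positive nuclei only.
#'
#' @param measurements output of [scoreNucleolus()].
#' @param manifest cohort manifest or `NULL`.
#' @param over `"all"` (default) or `"positives"`.
#' @return See [summarizeBySample()]; `value` in um^2.
#' @export
nucleolarAreaPerNucleus <- function(measurements, manifest = NULL,
                                    over = c("all", "positives")) {
  over <- match.arg(over)
  df <- measurements
  if (over == "positives") df <- df[df$positive %in% TRUE, ]
  summarizeBySample(df, "nucleolarAreaUm2", manifest)
}
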