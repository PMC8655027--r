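## mHTT (EM48) inclusion-body detection and the dispersal-ratio statistic:
## dispersal ratio = background-subtracted mean mHTT intensity in the
## nucleoplasm / mean in the inclusion. Higher ratio = more diffuse mHTT.

#' Inclusion detection parameters
#'
#' @param contrastMin an inclusion candidate must exceed `contrastMin` times
#'   the background-subtracted per-nucleus nucleoplasm estimate (median).
#'   The default 1.6 keeps inclusions detectable up to a dispersal ratio of
#'   ~0.6 while pixel noise plus the area floor suppresses false positives.
#' @param minAreaUm2 minimum inclusion area (um^2).
#' @param dilatePx inclusion masks are dilated by this many pixels before
#'   being excluded from the nucleoplasm.
#' @param ratioFrom `"brightest"`: the ratio uses the brightest inclusion
#'   (typical single EM48 body); `"weighted"`: area-weighted mean of all
#'   inclusions.
#' @param excludeNucleoli also exclude a nucleolar mask from the nucleoplasm
#'   (requires `nucleolarMask` in [detectInclusions()]).
#' @return Named parameter list for [detectInclusions()].
#' @export
inclusionParams <- function(contrastMin = 1.6, minAreaUm2 = 0.2,
                            dilatePx = 2L,
                            ratioFrom = c("brightest", "weighted"),
                            excludeNucleoli = FALSE) {
  list(contrastMin = contrastMin, minAreaUm2 = minAreaUm2,
       dilatePx = as.integer(dilatePx), ratioFrom = match.arg(ratioFrom),
       excludeNucleoli = excludeNucleoli)
}

#' Detect intranuclear mHTT inclusions and the dispersal ratio
#'
#' Inclusions are connected components of mHTT signal above
#' `contrastMin` times the nucleoplasm estimate with area at least
#' `minAreaUm2`. The nucleoplasm mask is the nucleus minus the dilated
#' inclusion masks (and, optionally, minus a nucleolar mask). Means are
#' background-subtracted by the field's modal intensity, so the ratio is
#' invariant under any positive channel gain.
#'
#' @param field an [ImageField-class] with an `mHTT` channel.
#' @param nuclei a [NucleusSet-class].
#' @param params parameters from [inclusionParams()].
#' @param nucleolarMask optional logical matrix of nucleolar territory to
#'   exclude when `excludeNucleoli` is set.
#' @param channel mHTT channel name.
#' @return `data.frame`, one row per nucleus: `fieldId`, `nucleusId`,
#'   `hasInclusion`, `nInclusions`, `inclusionAreaUm2` (mean per inclusion),
#'   `dispersalRatio` (`NA` unless `hasInclusion`), `nucleoplasmMean`,
#'   `inclusionMean`, `valid` (`FALSE` when the nucleoplasm mask came up
#'   empty).
#' @export
detectInclusions <- function(field, nuclei, params = inclusionParams(),
                             nucleolarMask = NULL, channel = "mHTT") {
  if (!channel %in% channelNames(field))
    stop("channel '", channel, "' not present in field")
  img <- getChannel(field, channel)
  lab <- labelMask(nuclei)
  tab <- nucleusTable(nuclei)
  pxs <- pixelSize(nuclei)
  sh <- dim(img)
  n <- nrow(tab)

  out <- data.frame(fieldId = rep_len(fieldId(nuclei), n),
                    nucleusId = tab$nucleusId,
                    hasInclusion = rep_len(FALSE, n),
                    nInclusions = rep_len(0L, n),
                    inclusionAreaUm2 = rep_len(NA_real_, n),
                    dispersalRatio = rep_len(NA_real_, n),
                    nucleoplasmMean = rep_len(NA_real_, n),
                    inclusionMean = rep_len(NA_real_, n),
                    valid = rep_len(TRUE, n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  bg <- .modalIntensity(img)
  pix <- which(lab > 0L)
  lp <- lab[pix]
  val <- img[pix]
  fl <- factor(lp, levels = seq_len(n))
  npMed <- as.numeric(tapply(val, fl, stats::median))
  npSub <- pmax(npMed - bg, 1e-6)

  cand <- matrix(FALSE, sh[1], sh[2])
  cand[pix] <- (val - bg) >= params$contrastMin * npSub[lp]
  minAreaPx <- max(1L, ceiling(params$minAreaUm2 / pxs^2))

  excl <- matrix(FALSE, sh[1], sh[2])
  accIdx <- integer(0)
  compNuc <- integer(0)
  compArea <- integer(0)
  compMean <- numeric(0)
  if (any(cand)) {
    comp <- EBImage::bwlabel(cand)
    compData <- EBImage::imageData(comp)
    cpix <- which(compData > 0L)
    cl <- as.integer(compData[cpix])
    ncomp <- max(cl)
    compArea <- tabulate(cl, nbins = ncomp)
    compMean <- rowsum(img[cpix], factor(cl, levels = seq_len(ncomp)))[, 1] /
      compArea
    labAt <- lab[cpix]
    compNuc <- vapply(split(labAt, cl), function(v) {
      v <- v[v > 0L]
      if (!length(v)) return(0L)
      as.integer(names(which.max(table(v))))
    }, integer(1))
    accepted <- compNuc > 0L & compArea >= minAreaPx &
      (compMean - bg) >= params$contrastMin * npSub[pmax(compNuc, 1L)]
    accIdx <- which(accepted)
    if (length(accIdx)) {
      accMask <- matrix(FALSE, sh[1], sh[2])
      accMask[cpix[cl %in% accIdx]] <- TRUE
      brush <- EBImage::makeBrush(2L * params$dilatePx + 1L, shape = "disc")
      excl <- EBImage::imageData(EBImage::dilate(accMask, brush)) > 0
    }
  }
  if (params$excludeNucleoli && !is.null(nucleolarMask))
    excl <- excl | nucleolarMask

  ## nucleoplasm means per nucleus over nucleus minus exclusion zone
  keep <- !excl[pix]
  npCount <- as.integer(table(factor(lp[keep], levels = seq_len(n))))
  npSum <- as.numeric(tapply(val[keep], factor(lp[keep], levels = seq_len(n)),
                             sum))
  npMean <- ifelse(npCount > 0L, npSum / npCount - bg, NA_real_)

  if (length(accIdx)) {
    fAcc <- factor(compNuc[accIdx], levels = seq_len(n))
    nInc <- as.integer(table(fAcc))
    out$nInclusions <- nInc
    out$hasInclusion <- nInc > 0L
    meanArea <- as.numeric(tapply(compArea[accIdx], fAcc, mean))
    out$inclusionAreaUm2 <- meanArea * pxs^2
    for (i in which(out$hasInclusion)) {
      comps <- accIdx[compNuc[accIdx] == i]
      incMean <- if (params$ratioFrom == "brightest") {
        max(compMean[comps]) - bg
      } else {
        sum(compMean[comps] * compArea[comps]) / sum(compArea[comps]) - bg
      }
      out$inclusionMean[i] <- incMean
      if (npCount[i] == 0L) {
        out$valid[i] <- FALSE  # nucleoplasm vanished after exclusion
      } else {
        out$nucleoplasmMean[i] <- npMean[i]
        out$dispersalRatio[i] <- npMean[i] / incMean
      }
    }
  }
  out$nucleoplasmMean[is.na(out$nucleoplasmMean) & out$valid] <-
    npMean[is.na(out$nucleoplasmMean) & out$valid]
  out
}

#' Per-sample fraction of nuclei carrying an mHTT inclusion
#'
#' @param measurements output of [detectInclusions()].
#' @param manifest cohort manifest or `NULL` (per-field values).
#' @return See [summarizeBySample()].
#' @export
inclusionPrevalence <- function(measurements, manifest = NULL) {
  df <- measurements[measurements$valid, ]
  summarizeBySample(df, "hasInclusion", manifest)
}

#' Per-sample mean dispersal ratio
#'
#' Mean over inclusion-bearing nuclei per field, then over fields per
#' sample.
#'
#' @inheritParams inclusionPrevalence
#' @return See [summarizeBySample()].
#' @export
dispersalRatioSummary <- function(measurements, manifest = NULL) {
  df <- measurements[measurements$valid & measurements$hasInclusion, ]
  summarizeBySample(df, "dispersalRatio", manifest)
}

.bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Intensity line scan across a field
#'
#' Samples the named channels along the segment from `p0` to `p1` by
#' bilinear interpolation at at most 0.5-pixel spacing and normalizes each
#' channel to its maximum along the segment.
#'
#' @param field an [ImageField-class].
#' @param p0,p1 segment end points as (row, col) pixel coordinates.
#' @param channels channels to profile (default: all).
#' @param spacingPx sample spacing in pixels (<= 0.5 recommended).
#' @return `data.frame` with strictly increasing `positionUm` and one
#'   normalized-intensity column (in \[0, 1\]) per channel.
#' @export
lineScan <- function(field, p0, p1, channels = NULL, spacingPx = 0.5) {
  if (is.null(channels)) channels <- channelNames(field)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length line-scan segment")
  nStep <- max(2L, ceiling(len / spacingPx) + 1L)
  t <- seq(0, 1, length.out = nStep)
  rr <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  out <- data.frame(positionUm = t * len * pixelSize(field))
  for (ch in channels) {
    v <- .bilinear(getChannel(field, ch), rr, cc)
    mx <- max(v)
    out[[ch]] <- if (mx > 0) v / mx else v
  }
  out
}
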