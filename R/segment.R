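## DAPI nucleus segmentation.
## Chain: Gaussian smooth -> Otsu threshold -> hole fill -> distance-transform
## watershed to split touching nuclei -> area filter -> border exclusion.
## Deterministic given the field and parameters; group/genotype metadata
## never reaches this module.

#' Segmentation parameters
#'
#' Area bounds follow the tissue: brain nuclei are accepted in
#' \[20, 400\] um^2, muscle nuclei in \[10, 150\] um^2. Thresholding is
#' data-driven (Otsu), so rescaling all intensities by a positive gain
#' leaves the masks unchanged.
#'
#' @param tissueMode `"brain"` or `"muscle"`; sets default area bounds.
#' @param blurSigma Gaussian smoothing sigma in pixels.
#' @param minAreaUm2,maxAreaUm2 accepted nucleus area range in um^2
#'   (defaults depend on `tissueMode`).
#' @param excludeBorder drop nuclei touching the field border.
#' @param splitTouching apply distance-transform watershed to separate
#'   touching nuclei.
#' @param watershedTolerance minimum object depth passed to the watershed.
#' @return Named list of parameters for [segmentNuclei()].
#' @export
segmentParams <- function(tissueMode = c("brain", "muscle"), blurSigma = 2,
                          minAreaUm2 = NULL, maxAreaUm2 = NULL,
                          excludeBorder = TRUE, splitTouching = TRUE,
                          watershedTolerance = 1) {
  tissueMode <- match.arg(tissueMode)
  if (is.null(minAreaUm2)) minAreaUm2 <- if (tissueMode == "brain") 20 else 10
  if (is.null(maxAreaUm2)) maxAreaUm2 <- if (tissueMode == "brain") 400 else 150
  list(tissueMode = tissueMode, blurSigma = blurSigma,
       minAreaUm2 = minAreaUm2, maxAreaUm2 = maxAreaUm2,
       excludeBorder = excludeBorder, splitTouching = splitTouching,
       watershedTolerance = watershedTolerance)
}

#' Segment DAPI-positive nuclei in a field
#'
#' @param field an [ImageField-class] with a `DAPI` channel.
#' @param params parameter list from [segmentParams()].
#' @return A [NucleusSet-class]. A field with no detectable nuclei yields an
#'   empty set (zero nuclei), not an error; a missing DAPI channel is a
#'   configuration error.
#' @examples
#' sim <- simulateField(fieldSpec(nNuclei = 5, seed = 3))
#' ns <- segmentNuclei(sim$field)
#' nrow(nucleusTable(ns))
#' @export
segmentNuclei <- function(field, params = segmentParams()) {
  if (!"DAPI" %in% channelNames(field))
    stop("configuration error: field has no DAPI channel")
  dapi <- getChannel(field, "DAPI")
  pxs <- pixelSize(field)
  sh <- dim(dapi)

  emptySet <- function() new("NucleusSet",
    labels = matrix(0L, sh[1], sh[2]),
    nuclei = data.frame(nucleusId = integer(), centroidRow = numeric(),
                        centroidCol = numeric(), areaPx = integer(),
                        areaUm2 = numeric(), meanDapi = numeric()),
    pixelSize = pxs, fieldId = fieldId(field))

  if (stats::sd(dapi) == 0) return(emptySet())

  img <- EBImage::Image(dapi / 65535)
  sm <- EBImage::gblur(img, sigma = params$blurSigma)
  thr <- EBImage::otsu(sm, range = range(sm))
  mask <- sm > thr
  mask <- EBImage::fillHull(mask)
  labels <- if (params$splitTouching) {
    dm <- EBImage::distmap(mask)
    EBImage::watershed(dm, tolerance = params$watershedTolerance, ext = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- as.integer(EBImage::imageData(labels))
  nlab <- max(lab)
  if (nlab == 0L) return(emptySet())

  pix <- which(lab > 0L)
  lp <- lab[pix]
  rows <- ((pix - 1L) %% sh[1]) + 1L
  cols <- ((pix - 1L) %/% sh[1]) + 1L
  areaPx <- tabulate(lp, nbins = nlab)
  cRow <- rowsum(rows, lp)[, 1] / areaPx
  cCol <- rowsum(cols, lp)[, 1] / areaPx
  meanD <- rowsum(dapi[pix], lp)[, 1] / areaPx
  areaUm2 <- areaPx * pxs^2

  keep <- areaUm2 >= params$minAreaUm2 & areaUm2 <= params$maxAreaUm2
  if (params$excludeBorder) {
    border <- rows == 1L | rows == sh[1] | cols == 1L | cols == sh[2]
    touching <- unique(lp[border])
    keep[touching] <- FALSE
  }
  keepIds <- which(keep)
  if (!length(keepIds)) return(emptySet())

  newId <- integer(nlab)
  newId[keepIds] <- seq_along(keepIds)
  out <- matrix(0L, sh[1], sh[2])
  sel <- newId[lp] > 0L
  out[pix[sel]] <- newId[lp[sel]]

  tab <- data.frame(nucleusId = seq_along(keepIds),
                    centroidRow = cRow[keepIds], centroidCol = cCol[keepIds],
                    areaPx = areaPx[keepIds], areaUm2 = areaUm2[keepIds],
                    meanDapi = meanD[keepIds])
  new("NucleusSet", labels = out, nuclei = tab, pixelSize = pxs,
      fieldId = fieldId(field))
}

#' Mean nuclear area of a segmentation
#'
#' @param nuclei a [NucleusSet-class] or its nucleus table.
#' @return Mean per-nucleus area in um^2; `NA` for an empty set (an
#'   undefined value, not zero).
#' @export
nucleusAreaSummary <- function(nuclei) {
  tab <- if (is(nuclei, "NucleusSet")) nucleusTable(nuclei) else nuclei
  if (nrow(tab) == 0L) return(NA_real_)
  mean(tab$areaUm2)
}

#' Match segmented nuclei to simulated ground truth
#'
#' Greedy nearest-centroid matching: each truth nucleus is matched to at
#' most one detection within `maxDistUm` (default: the truth radius).
#'
#' @param nuclei a [NucleusSet-class].
#' @param truth ground-truth table from [simulateField()] (same field).
#' @param maxDistUm match radius in micrometres; `NULL` uses each truth
#'   nucleus's own radius.
#' @return List with `matches` (data.frame truthId, nucleusId, distUm),
#'   `nTruth`, `nDetected`, `precision`, `recall`, `f1`.
#' @export
matchNuclei <- function(nuclei, truth, maxDistUm = NULL) {
  tab <- nucleusTable(nuclei)
  pxs <- pixelSize(nuclei)
  nT <- nrow(truth); nD <- nrow(tab)
  if (nT == 0L || nD == 0L) {
    f1 <- if (nT == 0L && nD == 0L) 1 else 0
    return(list(matches = data.frame(truthId = integer(),
                                     nucleusId = integer(), distUm = numeric()),
                nTruth = nT, nDetected = nD, precision = f1, recall = f1,
                f1 = f1))
  }
  d <- sqrt(outer(truth$centerRow, tab$centroidRow, "-")^2 +
            outer(truth$centerCol, tab$centroidCol, "-")^2) * pxs
  lim <- if (is.null(maxDistUm)) truth$radiusUm else rep_len(maxDistUm, nT)
  d[d > matrix(lim, nT, nD)] <- Inf
  matches <- list()
  repeat {
    i <- which.min(d)
    if (!length(i) || !is.finite(d[i])) break
    ti <- ((i - 1L) %% nT) + 1L
    di <- ((i - 1L) %/% nT) + 1L
    matches[[length(matches) + 1L]] <- data.frame(
      truthId = truth$nucleusId[ti], nucleusId = tab$nucleusId[di],
      distUm = d[i])
    d[ti, ] <- Inf
    d[, di] <- Inf
  }
  m <- if (length(matches)) do.call(rbind, matches) else
    data.frame(truthId = integer(), nucleusId = integer(), distUm = numeric())
  tp <- nrow(m)
  precision <- tp / nD
  recall <- tp / nT
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(matches = m, nTruth = nT, nDetected = nD, precision = precision,
       recall = recall, f1 = f1)
}

#' @rdname labelMask
#' @export
setMethod("labelMask", "NucleusSet", function(x) x@labels)

#' @rdname nucleusTable
#' @export
setMethod("nucleusTable", "NucleusSet", function(x) x@nuclei)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "NucleusSet", function(x) x@pixelSize)

#' @rdname fieldId
#' @export
setMethod("fieldId", "NucleusSet", function(x) x@fieldId)

setMethod("length", "NucleusSet", function(x) nrow(x@nuclei))

setMethod("show", "NucleusSet", function(object) {
  cat("NucleusSet for field '", object@fieldId, "': ", nrow(object@nuclei),
      " nuclei", sep = "")
  if (nrow(object@nuclei))
    cat(", mean area ", round(mean(object@nuclei$areaUm2), 1), " um^2",
        sep = "")
  cat("\n")
})
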