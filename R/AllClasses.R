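#' @import methods
NULL

.validProb <- function(p) is.numeric(p) && length(p) == 1L && !is.na(p) &&
  p >= 0 && p <= 1

#' FieldSpec: parameters of one synthetic microscopy field
#'
#' A `FieldSpec` fully determines one simulated multi-channel field
#' (together with its random seed): tissue geometry, nucleus number and
#' size, the per-marker nucleolar state model, the mutant-huntingtin (mHTT)
#' inclusion model, and the camera noise model. Build instances with
#' [fieldSpec()].
#'
#' @slot tissueMode `"brain"` (dense round nuclei) or `"muscle"` (sparse
#'   elongated nuclei along fiber boundaries over a striated background).
#' @slot fieldShape integer (rows, cols) of the raster.
#' @slot pixelSize micrometres per pixel.
#' @slot nNuclei number of nuclei to place.
#' @slot nucleusRadius numeric (mean, sd) equivalent radius in micrometres.
#' @slot nucleusAspect major/minor axis ratio (1 = circular).
#' @slot markers named list (`NPM1`, `NCL`), each a list with elements
#'   `positiveFraction`, `contrast`, `ringMode` (`"disk"`/`"annulus"`),
#'   `coreFraction`, `nucleolusRadius` (um), `nucleoliRange` (int 2),
#'   `nucleoplasmLevel` (intensity units).
#' @slot inclusionFraction probability that a nucleus carries one mHTT
#'   inclusion body.
#' @slot inclusionRadius inclusion body radius, micrometres.
#' @slot dispersalRatioMean,dispersalRatioSd normal law of the true
#'   nucleoplasm/inclusion mean-intensity ratio (truncated just above 0).
#' @slot nclRatioCorrelation correlation between the per-nucleus NCL
#'   intensity multiplier and the true dispersal ratio (0 = independent).
#' @slot backgroundLevel,dapiLevel,mhttNucleoplasmLevel intensity units.
#' @slot cellVariabilityCv coefficient of variation of per-nucleus
#'   brightness multipliers.
#' @slot gaussianSigma read-noise standard deviation, intensity units.
#' @slot poissonScale photons per intensity unit (`Inf` = no shot noise).
#' @slot overlapTolerance allowed fractional overlap of nucleus placements.
#' @slot maxPlacementRetries placement attempts per nucleus before failing.
#' @slot seed integer RNG seed making the field reproducible.
#' @seealso [fieldSpec()], [simulateField()]
#' @export
setClass("FieldSpec", representation(
  tissueMode = "character",
  fieldShape = "integer",
  pixelSize = "numeric",
  nNuclei = "integer",
  nucleusRadius = "numeric",
  nucleusAspect = "numeric",
  markers = "list",
  inclusionFraction = "numeric",
  inclusionRadius = "numeric",
  dispersalRatioMean = "numeric",
  dispersalRatioSd = "numeric",
  nclRatioCorrelation = "numeric",
  backgroundLevel = "numeric",
  dapiLevel = "numeric",
  mhttNucleoplasmLevel = "numeric",
  cellVariabilityCv = "numeric",
  gaussianSigma = "numeric",
  poissonScale = "numeric",
  overlapTolerance = "numeric",
  maxPlacementRetries = "integer",
  seed = "integer"
))

setValidity("FieldSpec", function(object) {
  msg <- character()
  if (!object@tissueMode %in% c("brain", "muscle"))
    msg <- c(msg, "tissueMode must be 'brain' or 'muscle'")
  if (length(object@fieldShape) != 2L || any(object@fieldShape < 32L))
    msg <- c(msg, "fieldShape must be two integers >= 32")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@nNuclei < 0L) msg <- c(msg, "nNuclei must be >= 0")
  if (length(object@nucleusRadius) != 2L || object@nucleusRadius[1] <= 0 ||
      object@nucleusRadius[2] < 0)
    msg <- c(msg, "nucleusRadius must be (mean > 0, sd >= 0)")
  if (object@nucleusAspect < 1)
    msg <- c(msg, "nucleusAspect must be >= 1")
  for (mk in names(object@markers)) {
    m <- object@markers[[mk]]
    if (!.validProb(m$positiveFraction))
      msg <- c(msg, sprintf("markers$%s$positiveFraction must be in [0,1]", mk))
    if (!is.numeric(m$contrast) || m$contrast < 1)
      msg <- c(msg, sprintf("markers$%s$contrast must be >= 1", mk))
    if (!m$ringMode %in% c("disk", "annulus"))
      msg <- c(msg, sprintf("markers$%s$ringMode must be 'disk' or 'annulus'", mk))
    if (!is.numeric(m$nucleolusRadius) || m$nucleolusRadius <= 0)
      msg <- c(msg, sprintf("markers$%s$nucleolusRadius must be > 0", mk))
    if (length(m$nucleoliRange) != 2L || m$nucleoliRange[1] < 1 ||
        m$nucleoliRange[2] < m$nucleoliRange[1])
      msg <- c(msg, sprintf("markers$%s$nucleoliRange must be a valid count range", mk))
  }
  if (!.validProb(object@inclusionFraction))
    msg <- c(msg, "inclusionFraction must be in [0,1]")
  if (object@inclusionRadius <= 0) msg <- c(msg, "inclusionRadius must be > 0")
  if (object@dispersalRatioMean < 0)
    msg <- c(msg, "dispersalRatioMean must be >= 0")
  if (object@dispersalRatioSd < 0)
    msg <- c(msg, "dispersalRatioSd must be >= 0")
  if (abs(object@nclRatioCorrelation) > 1)
    msg <- c(msg, "nclRatioCorrelation must be in [-1,1]")
  if (object@backgroundLevel < 0 || object@gaussianSigma < 0)
    msg <- c(msg, "backgroundLevel and gaussianSigma must be >= 0")
  if (object@poissonScale <= 0)
    msg <- c(msg, "poissonScale must be > 0 (use Inf for noise-free)")
  if (!.validProb(object@overlapTolerance))
    msg <- c(msg, "overlapTolerance must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' ImageField: one multi-channel 2-D fluorescence field
#'
#' The unit of acquisition: a rows x cols x channels intensity array with a
#' channel map and physical pixel size. Intensities are stored as floating
#' point in \[0, 65535\]; rounding to 16-bit happens only at TIFF write time.
#'
#' @slot imageData numeric array (rows, cols, channels).
#' @slot channelNames character vector naming the third dimension.
#' @slot pixelSize micrometres per pixel.
#' @slot fieldId character scalar identifying the field.
#' @slot sampleId character scalar identifying the biological sample
#'   (animal/patient/well); `NA` when unknown.
#' @seealso [simulateField()], [readImageField()], [getChannel()]
#' @export
setClass("ImageField", representation(
  imageData = "array",
  channelNames = "character",
  pixelSize = "numeric",
  fieldId = "character",
  sampleId = "character"
))

setValidity("ImageField", function(object) {
  d <- dim(object@imageData)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "imageData must be a 3-D array (rows, cols, channels)")
  else if (length(object@channelNames) != d[3])
    msg <- c(msg, "channelNames must match the number of channels")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' NucleusSet: a field's segmented DAPI-positive nuclei
#'
#' Holds the integer label raster (0 = background) plus a per-nucleus
#' feature table. Masks are pairwise disjoint by construction and, with the
#' default parameters, border-touching nuclei are excluded.
#'
#' @slot labels integer matrix in field coordinates.
#' @slot nuclei `data.frame` with columns `nucleusId`, `centroidRow`,
#'   `centroidCol` (pixels, 1-based), `areaPx`, `areaUm2`, `meanDapi`.
#' @slot pixelSize micrometres per pixel.
#' @slot fieldId field the segmentation belongs to.
#' @seealso [segmentNuclei()]
#' @export
setClass("NucleusSet", representation(
  labels = "matrix",
  nuclei = "data.frame",
  pixelSize = "numeric",
  fieldId = "character"
))

setValidity("NucleusSet", function(object) {
  msg <- character()
  labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
  ids <- sort(object@nuclei$nucleusId)
  if (!identical(labs, as.integer(ids)))
    msg <- c(msg, "label raster and nucleus table ids disagree")
  if (any(object@labels < 0)) msg <- c(msg, "labels must be >= 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: one statistical group comparison
#'
#' Produced by [mwuTest()], [kruskalDunn()] and [pearsonR()]. Carries the
#' per-sample values per group, the test statistic, raw (and, for
#' Kruskal-Wallis/Dunn, adjusted pairwise) p-values, group means with SEM,
#' and for two-group comparisons the relative difference of group means,
#' `100 * (1 - mean_B / mean_A)`.
#'
#' @slot measure name of the compared quantity.
#' @slot test one of `"MWU"`, `"KW_Dunn"`, `"Pearson"`.
#' @slot groups named list of per-sample numeric vectors.
#' @slot statistic named numeric (e.g. `U`, `H`, `r`).
#' @slot p omnibus / two-group p-value.
#' @slot pairwise `data.frame` of pairwise Dunn contrasts (may be empty).
#' @slot groupMeans,groupSEM named numeric summaries per group.
#' @slot relDiff percent relative difference (two-group case, else `NA`).
#' @export
setClass("ComparisonResult", representation(
  measure = "character",
  test = "character",
  groups = "list",
  statistic = "numeric",
  p = "numeric",
  pairwise = "data.frame",
  groupMeans = "numeric",
  groupSEM = "numeric",
  relDiff = "numeric"
))

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (!object@test %in% c("MWU", "KW_Dunn", "Pearson"))
    msg <- c(msg, "test must be MWU, KW_Dunn or Pearson")
  if (length(object@p) != 1L || is.na(object@p) ||
      object@p <= 0 || object@p > 1)
    msg <- c(msg, "p must lie in (0, 1]")
  if (nrow(object@pairwise) &&
      any(object@pairwise$pAdj + 1e-12 < object@pairwise$p))
    msg <- c(msg, "adjusted p must be >= raw p")
  if (length(msg)) msg else TRUE
})
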