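#' Default per-marker nucleolar parameters
#'
#' NPM1 (nucleophosmin, granular component) is rendered as an annulus with a
#' dimmer fibrillar-center core; NCL (nucleolin) as a filled disk. Contrast
#' is the nucleolar-to-nucleoplasmic mean ratio.
#'
#' @param positiveFraction probability a nucleus is in the "nucleolar" state
#'   (vs "delocalized", where the marker is uniform over the nucleoplasm).
#' @param contrast nucleolar/nucleoplasm mean-intensity ratio (>= 1).
#' @param ringMode `"annulus"` or `"disk"`.
#' @param coreFraction annulus core intensity as a fraction of rim intensity.
#' @param nucleolusRadius nucleolus radius, micrometres.
#' @param nucleoliRange integer (min, max) nucleoli per positive nucleus.
#' @param nucleoplasmLevel diffuse nucleoplasmic marker intensity.
#' @return Named list of marker parameters.
#' @export
markerSpec <- function(positiveFraction = 0.6, contrast = 3,
                       ringMode = c("annulus", "disk"), coreFraction = 0.4,
                       nucleolusRadius = 0.8, nucleoliRange = c(1L, 3L),
                       nucleoplasmLevel = 1000) {
  list(positiveFraction = positiveFraction, contrast = contrast,
       ringMode = match.arg(ringMode), coreFraction = coreFraction,
       nucleolusRadius = nucleolusRadius,
       nucleoliRange = as.integer(nucleoliRange),
       nucleoplasmLevel = nucleoplasmLevel)
}

#' Construct a FieldSpec
#'
#' Defaults describe a confocal-regime brain field: 512 x 512 pixels at
#' 0.1 um/pixel with round nuclei of 3 um mean radius. `tissueMode =
#' "muscle"` switches to sparser, elongated (aspect 1.8) peripheral nuclei
#' of 2.5 um mean radius lying along vertical fiber boundaries over a
#' faintly striated background, with muscle-appropriate size bounds applied
#' later at segmentation.
#'
#' @param tissueMode `"brain"` or `"muscle"`.
#' @param fieldShape integer (rows, cols).
#' @param pixelSize micrometres per pixel.
#' @param nNuclei nuclei to place (default 30 brain, 12 muscle).
#' @param nucleusRadius numeric (mean, sd) in micrometres (default
#'   `c(3, 0.3)` brain, `c(2.5, 0.25)` muscle).
#' @param nucleusAspect major/minor axis ratio (default 1 brain, 1.8 muscle).
#' @param markers named list with elements `NPM1` and `NCL`, each as
#'   returned by [markerSpec()]. Partial lists are completed with defaults.
#' @param inclusionFraction probability of one mHTT inclusion per nucleus.
#' @param inclusionRadius inclusion radius, micrometres.
#' @param dispersalRatioMean,dispersalRatioSd normal law of the true
#'   nucleoplasm/inclusion intensity ratio, truncated just above zero.
#' @param nclRatioCorrelation per-nucleus correlation between NCL intensity
#'   and dispersal ratio (models nucleolar integrity coupling).
#' @param backgroundLevel,dapiLevel,mhttNucleoplasmLevel intensity units.
#' @param cellVariabilityCv CV of per-nucleus brightness multipliers.
#' @param gaussianSigma Gaussian read noise sd (intensity units).
#' @param poissonScale photons per intensity unit; `Inf` disables shot noise.
#' @param overlapTolerance allowed fractional overlap between nuclei.
#' @param maxPlacementRetries placement attempts per nucleus.
#' @param seed integer seed; the same spec and seed give bit-identical output.
#' @return A validated [FieldSpec-class] object.
#' @examples
#' sp <- fieldSpec(nNuclei = 10, seed = 1)
#' sim <- simulateField(sp)
#' dim(sim$field@imageData)
#' @export
fieldSpec <- function(tissueMode = c("brain", "muscle"),
                      fieldShape = c(512L, 512L), pixelSize = 0.1,
                      nNuclei = NULL, nucleusRadius = NULL,
                      nucleusAspect = NULL, markers = list(),
                      inclusionFraction = 0, inclusionRadius = 0.6,
                      dispersalRatioMean = 0.4, dispersalRatioSd = 0.1,
                      nclRatioCorrelation = 0,
                      backgroundLevel = 200, dapiLevel = 5000,
                      mhttNucleoplasmLevel = 800, cellVariabilityCv = 0.1,
                      gaussianSigma = 20, poissonScale = 0.1,
                      overlapTolerance = 0.1, maxPlacementRetries = 500L,
                      seed = 1L) {
  tissueMode <- match.arg(tissueMode)
  if (is.null(nNuclei)) nNuclei <- if (tissueMode == "brain") 30L else 12L
  if (is.null(nucleusRadius))
    nucleusRadius <- if (tissueMode == "brain") c(3, 0.3) else c(2.5, 0.25)
  if (is.null(nucleusAspect))
    nucleusAspect <- if (tissueMode == "brain") 1 else 1.8
  base <- list(NPM1 = markerSpec(ringMode = "annulus"),
               NCL = markerSpec(ringMode = "disk"))
  for (mk in names(markers)) {
    if (!mk %in% names(base))
      stop("unknown marker '", mk, "'; expected NPM1 or NCL")
    base[[mk]] <- utils::modifyList(base[[mk]], markers[[mk]])
  }
  new("FieldSpec", tissueMode = tissueMode,
      fieldShape = as.integer(fieldShape), pixelSize = pixelSize,
      nNuclei = as.integer(nNuclei), nucleusRadius = as.numeric(nucleusRadius),
      nucleusAspect = nucleusAspect, markers = base,
      inclusionFraction = inclusionFraction, inclusionRadius = inclusionRadius,
      dispersalRatioMean = dispersalRatioMean,
      dispersalRatioSd = dispersalRatioSd,
      nclRatioCorrelation = nclRatioCorrelation,
      backgroundLevel = backgroundLevel, dapiLevel = dapiLevel,
      mhttNucleoplasmLevel = mhttNucleoplasmLevel,
      cellVariabilityCv = cellVariabilityCv, gaussianSigma = gaussianSigma,
      poissonScale = poissonScale, overlapTolerance = overlapTolerance,
      maxPlacementRetries = as.integer(maxPlacementRetries),
      seed = as.integer(seed))
}

#' Derive a modified copy of a FieldSpec
#'
#' Applies named overrides to an existing spec; `markers` overrides are
#' merged per marker. Used to express group differences in a cohort.
#'
#' @param spec a [FieldSpec-class].
#' @param ... named `fieldSpec()` arguments to override.
#' @return A new validated `FieldSpec`.
#' @export
updateSpec <- function(spec, ...) {
  ov <- list(...)
  cur <- list(tissueMode = spec@tissueMode, fieldShape = spec@fieldShape,
              pixelSize = spec@pixelSize, nNuclei = spec@nNuclei,
              nucleusRadius = spec@nucleusRadius,
              nucleusAspect = spec@nucleusAspect, markers = spec@markers,
              inclusionFraction = spec@inclusionFraction,
              inclusionRadius = spec@inclusionRadius,
              dispersalRatioMean = spec@dispersalRatioMean,
              dispersalRatioSd = spec@dispersalRatioSd,
              nclRatioCorrelation = spec@nclRatioCorrelation,
              backgroundLevel = spec@backgroundLevel,
              dapiLevel = spec@dapiLevel,
              mhttNucleoplasmLevel = spec@mhttNucleoplasmLevel,
              cellVariabilityCv = spec@cellVariabilityCv,
              gaussianSigma = spec@gaussianSigma,
              poissonScale = spec@poissonScale,
              overlapTolerance = spec@overlapTolerance,
              maxPlacementRetries = spec@maxPlacementRetries,
              seed = spec@seed)
  if ("markers" %in% names(ov)) {
    mk <- cur$markers
    for (m in names(ov$markers)) mk[[m]] <- utils::modifyList(mk[[m]], ov$markers[[m]])
    ov$markers <- NULL
    cur$markers <- mk
  }
  cur[names(ov)] <- ov
  # markers already merged: bypass fieldSpec() marker defaults by direct merge
  args <- cur
  args$markers <- lapply(cur$markers, function(m) m)
  do.call(fieldSpec, args)
}

setMethod("show", "FieldSpec", function(object) {
  cat("FieldSpec (", object@tissueMode, " mode)\n", sep = "")
  cat("  field: ", paste(object@fieldShape, collapse = " x "),
      " px at ", object@pixelSize, " um/px\n", sep = "")
  cat("  nuclei: ", object@nNuclei, " of r ", object@nucleusRadius[1],
      " +/- ", object@nucleusRadius[2], " um (aspect ",
      round(object@nucleusAspect, 2), ")\n", sep = "")
  for (mk in names(object@markers)) {
    m <- object@markers[[mk]]
    cat("  ", mk, ": P(nucleolar)=", m$positiveFraction, ", contrast ",
        m$contrast, "x, ", m$ringMode, ", r=", m$nucleolusRadius, " um\n",
        sep = "")
  }
  cat("  inclusions: P=", object@inclusionFraction, ", ratio ",
      object@dispersalRatioMean, " +/- ", object@dispersalRatioSd,
      "\n  noise: poissonScale=", object@poissonScale, ", gaussianSigma=",
      object@gaussianSigma, ", seed=", object@seed, "\n", sep = "")
})
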