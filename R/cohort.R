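#' Simulate and measure a cohort without keeping rasters
#'
#' Streams over the cohort manifest: each field is simulated, segmented and
#' scored, then its raster is discarded, so arbitrarily large cohorts run in
#' constant memory. Group labels live only in the manifest and never reach
#' the measurement calls.
#'
#' @inheritParams cohortManifest
#' @param markers nucleolar marker channels to score.
#' @param inclusions also run inclusion detection on the mHTT channel.
#' @param segParamsBy named list of [segmentParams()] per group, or a single
#'   parameter list applied to all groups; `NULL` picks defaults from each
#'   group spec's tissue mode.
#' @return List with `nuclei`, `nucleolar` (all markers, long),
#'   `inclusions` (or `NULL`), `truth`, `manifest`.
#' @examples
#' gs <- list(g = fieldSpec(nNuclei = 6))
#' res <- analyzeCohort(gs, 1, 2, seed = 1)
#' fractionPositive(res$nucleolar[res$nucleolar$marker == "NPM1", ],
#'                  res$manifest)
#' @export
analyzeCohort <- function(groupSpecs, samplesPerGroup, fieldsPerSample, seed,
                          markers = c("NPM1", "NCL"), inclusions = FALSE,
                          segParamsBy = NULL) {
  man <- cohortManifest(groupSpecs, samplesPerGroup, fieldsPerSample, seed)
  segBy <- lapply(names(groupSpecs), function(g) {
    if (is.null(segParamsBy))
      segmentParams(groupSpecs[[g]]@tissueMode)
    else if (!is.null(names(segParamsBy)) && g %in% names(segParamsBy))
      segParamsBy[[g]]
    else segParamsBy
  })
  names(segBy) <- names(groupSpecs)
  nucRows <- scoreRows <- incRows <- truthRows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    g <- man$group[i]
    sim <- simulateField(groupSpecs[[g]], seed = man$seed[i],
                         fieldId = man$fieldId[i], sampleId = man$sampleId[i])
    ns <- segmentNuclei(sim$field, segBy[[g]])
    tab <- nucleusTable(ns)
    if (nrow(tab)) tab <- cbind(fieldId = man$fieldId[i], tab)
    nucRows[[i]] <- tab
    scoreRows[[i]] <- do.call(rbind, lapply(markers, function(mk)
      scoreNucleolus(sim$field, ns, mk)))
    if (inclusions) incRows[[i]] <- detectInclusions(sim$field, ns)
    tt <- sim$truth
    tt$group <- rep_len(man$group[i], nrow(tt))
    tt$sampleId <- rep_len(man$sampleId[i], nrow(tt))
    truthRows[[i]] <- tt
  }
  list(nuclei = do.call(rbind, nucRows),
       nucleolar = do.call(rbind, scoreRows),
       inclusions = if (inclusions) do.call(rbind, incRows) else NULL,
       truth = do.call(rbind, truthRows), manifest = man)
}
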