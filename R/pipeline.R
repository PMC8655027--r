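## End-to-end orchestration: simulate (or read) -> segment -> score
## nucleolus/inclusion -> aggregate -> compare. Group labels are withheld
## from all measurement stages and joined only at the stats stage, so the
## per-nucleus measurements are structurally blind to genotype.

.specFromList <- function(lst) {
  ## YAML sequences arrive as lists; flatten the vector-valued arguments
  for (nm in intersect(c("fieldShape", "nucleusRadius"), names(lst)))
    if (is.list(lst[[nm]])) lst[[nm]] <- unlist(lst[[nm]])
  if (!is.null(lst$markers))
    lst$markers <- lapply(lst$markers, function(m) {
      if (!is.null(m$nucleoliRange) && is.list(m$nucleoliRange))
        m$nucleoliRange <- unlist(m$nucleoliRange)
      m
    })
  known <- names(formals(fieldSpec))
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop("unknown fieldSpec parameter(s): ", paste(bad, collapse = ", "))
  do.call(fieldSpec, lst)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Read a pipeline run configuration
#'
#' @param path YAML file with keys `seed`, `output`, `input` (either
#'   `simulate` with `base`/`groups`/`samplesPerGroup`/`fieldsPerSample`, or
#'   `images` with `dir`/`channelMap`/`manifest`), and optional parameter
#'   blocks `segment`, `nucleolus`, `inclusion`, `markers`.
#' @return The configuration list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' Run the full quantification pipeline
#'
#' Processes every field (streamed, so large cohorts never hold all rasters
#' in memory), writes the per-nucleus tables, per-sample summaries and
#' group comparisons, and a markdown report. The run is deterministic given
#' configuration and seed; the configuration is echoed verbatim into the
#' output directory.
#'
#' @param config configuration list (see [readRunConfig()]) or a YAML path.
#' @param outDir output directory (default: `config$output`).
#' @return Invisibly, a list with the result tables (`nuclei`, `nucleolar`,
#'   `inclusions`, `sampleSummary`, `comparisons`, `manifest`, `truth`) and
#'   `outDir`. Output files: `nuclei.csv`, `nucleolar.csv`,
#'   `inclusions.csv`, `sample_summary.csv`, `comparisons.csv`,
#'   `report.md`, `report.json`, `config.yaml`, plus `manifest.csv` and
#'   `truth.csv` for simulated input.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(outDir)) outDir <- config$output
  if (is.null(outDir)) stop("no output directory configured")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  markers <- if (is.null(config$markers)) c("NPM1", "NCL") else
    unlist(config$markers)

  simulateMode <- !is.null(config$input$simulate)
  truth <- NULL
  if (simulateMode) {
    simCfg <- config$input$simulate
    base <- if (is.null(simCfg$base)) list() else simCfg$base
    groupSpecs <- .stage("simulate", {
      gs <- lapply(simCfg$groups, function(ov) {
        merged <- if (is.null(ov)) base else utils::modifyList(base, ov)
        .specFromList(merged)
      })
      names(gs) <- names(simCfg$groups)
      gs
    })
    man <- cohortManifest(groupSpecs, simCfg$samplesPerGroup,
                          simCfg$fieldsPerSample, seed)
    getField <- function(i) {
      sim <- simulateField(groupSpecs[[man$group[i]]], seed = man$seed[i],
                           fieldId = man$fieldId[i],
                           sampleId = man$sampleId[i])
      truth[[i]] <<- sim$truth
      if (isTRUE(simCfg$writeImages)) {
        imgDir <- file.path(outDir, "images")
        dir.create(imgDir, showWarnings = FALSE)
        writeImageField(sim$field,
                        file.path(imgDir, paste0(man$fieldId[i], ".tif")))
      }
      sim$field
    }
    truth <- vector("list", nrow(man))
  } else if (!is.null(config$input$images)) {
    imCfg <- config$input$images
    cm <- .stage("input", readChannelMap(imCfg$channelMap))
    man <- .stage("input", utils::read.csv(imCfg$manifest,
                                           stringsAsFactors = FALSE))
    if (is.null(man$fieldId))
      man$fieldId <- sub("\\.tiff?$", "", basename(man$file))
    getField <- function(i)
      readImageField(file.path(imCfg$dir, man$file[i]), cm$channels,
                     cm$pixelSize, fieldId = man$fieldId[i],
                     sampleId = man$sampleId[i])
  } else {
    stop("config$input must define either 'simulate' or 'images'")
  }

  segPar <- do.call(segmentParams,
                    if (is.null(config$segment)) list() else config$segment)
  nucPar <- do.call(nucleolusParams,
                    if (is.null(config$nucleolus)) list() else config$nucleolus)
  incPar <- do.call(inclusionParams,
                    if (is.null(config$inclusion)) list() else config$inclusion)

  nucRows <- scoreRows <- incRows <- vector("list", nrow(man))
  inclusionSkipped <- FALSE
  for (i in seq_len(nrow(man))) {
    field <- .stage(if (simulateMode) "simulate" else "input", getField(i))
    ns <- .stage("segment", segmentNuclei(field, segPar))
    tab <- nucleusTable(ns)
    if (nrow(tab)) tab <- cbind(fieldId = man$fieldId[i], tab)
    nucRows[[i]] <- tab
    present <- intersect(markers, channelNames(field))
    scoreRows[[i]] <- .stage("nucleolus", do.call(rbind, lapply(
      present, function(mk) scoreNucleolus(field, ns, mk, nucPar))))
    if ("mHTT" %in% channelNames(field)) {
      incRows[[i]] <- .stage("inclusion", detectInclusions(field, ns, incPar))
    } else if (!inclusionSkipped) {
      message("inclusion stage skipped: no mHTT channel in input")
      inclusionSkipped <- TRUE
    }
  }

  nuclei <- do.call(rbind, nucRows)
  nucleolar <- do.call(rbind, scoreRows)
  inclusions <- do.call(rbind, incRows)
  utils::write.csv(nuclei, file.path(outDir, "nuclei.csv"),
                   row.names = FALSE)
  utils::write.csv(nucleolar, file.path(outDir, "nucleolar.csv"),
                   row.names = FALSE)
  if (!is.null(inclusions))
    utils::write.csv(inclusions, file.path(outDir, "inclusions.csv"),
                     row.names = FALSE)
  utils::write.csv(man, file.path(outDir, "manifest.csv"), row.names = FALSE)
  if (simulateMode) {
    truth <- do.call(rbind, truth)
    utils::write.csv(truth, file.path(outDir, "truth.csv"),
                     row.names = FALSE)
  }

  ## aggregate to per-sample values
  summaries <- .stage("stats", {
    ss <- list()
    for (mk in intersect(markers, unique(nucleolar$marker))) {
      mrows <- nucleolar[nucleolar$marker == mk, ]
      fp <- fractionPositive(mrows, man)
      fp$measure <- paste0("fractionPositive_", mk)
      ar <- nucleolarAreaPerNucleus(mrows, man)
      ar$measure <- paste0("nucleolarArea_", mk)
      ss <- c(ss, list(fp, ar))
    }
    if (nrow(nuclei)) {
      na <- summarizeBySample(nuclei, "areaUm2", man)
      na$measure <- "meanNuclearArea"
      ss <- c(ss, list(na))
    }
    if (!is.null(inclusions)) {
      ip <- inclusionPrevalence(inclusions, man)
      ip$measure <- "inclusionPrevalence"
      ss <- c(ss, list(ip))
      dr <- dispersalRatioSummary(inclusions, man)
      if (any(!is.na(dr$value))) {
        dr$measure <- "dispersalRatio"
        ss <- c(ss, list(dr))
      }
    }
    do.call(rbind, ss)
  })
  utils::write.csv(summaries, file.path(outDir, "sample_summary.csv"),
                   row.names = FALSE)

  comparisons <- .stage("stats", {
    rows <- list()
    results <- list()
    for (ms in unique(summaries$measure)) {
      ssm <- summaries[summaries$measure == ms & !is.na(summaries$value), ]
      counts <- table(ssm$group)
      if (length(counts) < 2L || any(counts < 2L)) next
      res <- compareGroups(ssm, measure = ms)
      results[[ms]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms, test = res@test,
        statistic = unname(res@statistic[1]), p = pValue(res),
        relDiffPct = relativeDifference(res), contrast = "",
        z = NA_real_, pAdj = NA_real_, stringsAsFactors = FALSE)
      pw <- pairwiseTable(res)
      if (nrow(pw))
        rows[[length(rows) + 1L]] <- data.frame(
          measure = ms, test = res@test, statistic = NA_real_,
          p = pw$p, relDiffPct = NA_real_,
          contrast = paste(pw$groupA, "vs", pw$groupB), z = pw$z,
          pAdj = pw$pAdj, stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows), results = results)
  })
  utils::write.csv(comparisons$table, file.path(outDir, "comparisons.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, comparisons = comparisons$table),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  .writeReport(summaries, comparisons$table, file.path(outDir, "report.md"))

  invisible(list(nuclei = nuclei, nucleolar = nucleolar,
                 inclusions = inclusions, sampleSummary = summaries,
                 comparisons = comparisons$table,
                 results = comparisons$results, manifest = man,
                 truth = truth, outDir = outDir))
}

## markdown report: per-measure group summaries (bar-figure style) + tests
.writeReport <- function(summaries, comparisons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Quantification report\n", con)
  for (ms in unique(summaries$measure)) {
    ssm <- summaries[summaries$measure == ms & !is.na(summaries$value), ]
    writeLines(paste0("## ", ms, "\n"), con)
    writeLines("| group | N samples | mean | SEM |", con)
    writeLines("|---|---|---|---|", con)
    for (g in unique(ssm$group)) {
      v <- ssm$value[ssm$group == g]
      writeLines(sprintf("| %s | %d | %.4g | %.3g |", g, length(v),
                         mean(v), .sem(v)), con)
    }
    cmp <- comparisons[comparisons$measure == ms, , drop = FALSE]
    if (nrow(cmp)) {
      main <- cmp[cmp$contrast == "", , drop = FALSE]
      if (nrow(main))
        writeLines(sprintf("\n%s: statistic %.4g, p = %.4g%s\n",
                           main$test[1], main$statistic[1], main$p[1],
                           ifelse(is.na(main$relDiffPct[1]), "",
                                  sprintf(", relative difference %.1f%%",
                                          main$relDiffPct[1]))), con)
      pw <- cmp[cmp$contrast != "", , drop = FALSE]
      if (nrow(pw))
        for (j in seq_len(nrow(pw)))
          writeLines(sprintf("- %s: z = %.3f, adjusted p = %.4g",
                             pw$contrast[j], pw$z[j], pw$pAdj[j]), con)
      writeLines("", con)
    }
  }
}
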