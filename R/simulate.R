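## Synthetic fluorescence-microscopy generator.
## Renders projected 2-D fields: hard geometric bodies (ellipse nuclei,
## disk/annulus nucleoli, disk inclusions) on a background, then camera
## noise: Poisson(poissonScale * signal) / poissonScale + N(0, gaussianSigma),
## clamped to [0, 65535]. Intensities stay floating point until TIFF write.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## linear indices of pixels whose centers fall inside a rotated ellipse
.ellipseIdx <- function(shape, cr, cc, a, b, theta) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(shape[1], ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(shape[2], ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dr <- matrix(rows - cr, nrow = length(rows), ncol = length(cols))
  dc <- matrix(cols - cc, nrow = length(rows), ncol = length(cols),
               byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ij <- which(inside, arr.ind = TRUE)
  (c0 - 1L + ij[, 2] - 1L) * shape[1] + (r0 - 1L + ij[, 1])
}

.diskIdx <- function(shape, cr, cc, r) .ellipseIdx(shape, cr, cc, r, r, 0)

## annulus split: list(rim=..., core=...) linear indices
.annulusIdx <- function(shape, cr, cc, r, coreFrac = 0.55) {
  all <- .diskIdx(shape, cr, cc, r)
  core <- .diskIdx(shape, cr, cc, coreFrac * r)
  list(rim = setdiff(all, core), core = core, all = all)
}

.placeNuclei <- function(spec) {
  n <- spec@nNuclei
  sh <- spec@fieldShape
  pxs <- spec@pixelSize
  rMean <- spec@nucleusRadius[1] / pxs
  rSd <- spec@nucleusRadius[2] / pxs
  asp <- spec@nucleusAspect
  tol <- spec@overlapTolerance
  radii <- pmax(0.4 * rMean, stats::rnorm(n, rMean, rSd))
  aMaj <- radii * sqrt(asp)
  rows <- cols <- theta <- numeric(n)
  fiberW <- 60  # px; vertical fiber period in muscle mode
  bounds <- if (spec@tissueMode == "muscle")
    seq(fiberW / 2, sh[2] - fiberW / 2, by = fiberW) else NULL
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(spec@maxPlacementRetries)) {
      a <- aMaj[i]
      if (spec@tissueMode == "muscle") {
        cc <- sample(bounds, 1L) + stats::rnorm(1, 0, 3)
        cc <- min(max(cc, a + 2), sh[2] - a - 1)
        cr <- stats::runif(1, a + 2, sh[1] - a - 1)
        th <- stats::rnorm(1, pi / 2, 0.15)  # long axis along the fiber
      } else {
        cr <- stats::runif(1, a + 2, sh[1] - a - 1)
        cc <- stats::runif(1, a + 2, sh[2] - a - 1)
        th <- stats::runif(1, 0, pi)
      }
      ok <- TRUE
      if (i > 1L) {
        d <- sqrt((rows[seq_len(i - 1L)] - cr)^2 +
                  (cols[seq_len(i - 1L)] - cc)^2)
        ok <- all(d >= (1 - tol) * (aMaj[seq_len(i - 1L)] + a))
      }
      if (ok) {
        rows[i] <- cr; cols[i] <- cc; theta[i] <- th
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      dens <- sum(pi * radii[seq_len(n)]^2) / prod(sh)
      stop(sprintf(paste0("nucleus placement failed after %d retries: ",
                          "requested density %.0f%% of field area is too ",
                          "high for non-overlapping placement"),
                   spec@maxPlacementRetries, 100 * dens))
    }
  }
  data.frame(row = rows, col = cols, radiusPx = radii, theta = theta)
}

## place k nucleoli (radius rn px) strictly inside an ellipse nucleus
.placeNucleoli <- function(k, cr, cc, a, b, theta, rn) {
  ## shrink the body to fit unusually small nuclei rather than failing
  rn <- min(rn, max(0.5, b - 1.5))
  rhoMax <- 1 - (rn + 1) / b
  out <- matrix(NA_real_, k, 3, dimnames = list(NULL, c("row", "col", "radPx")))
  for (j in seq_len(k)) {
    for (try in 1:20) {
      phi <- stats::runif(1, 0, 2 * pi)
      rho <- sqrt(stats::runif(1)) * rhoMax
      u <- rho * a * cos(phi); v <- rho * b * sin(phi)
      pr <- cr + u * cos(theta) - v * sin(theta)
      pc <- cc + u * sin(theta) + v * cos(theta)
      if (j == 1L ||
          all(sqrt((out[seq_len(j - 1L), 1] - pr)^2 +
                   (out[seq_len(j - 1L), 2] - pc)^2) >= 1.8 * rn))
        break
    }
    out[j, ] <- c(pr, pc, rn)
  }
  out
}

.encodeBodies <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return("")
  paste(apply(m, 1, function(r)
    sprintf("%.2f:%.2f:%.2f", r[1], r[2], r[3])), collapse = ";")
}

#' Parse a nucleolus/inclusion geometry string from a ground-truth table
#'
#' @param s string of `row:col:radiusPx` triplets separated by `;`.
#' @return Numeric matrix with columns `row`, `col`, `radPx` (0 rows if empty).
#' @export
parseBodies <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("row", "col", "radPx"))))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.numeric))
  colnames(m) <- c("row", "col", "radPx")
  m
}

.backgroundField <- function(spec) {
  sh <- spec@fieldShape
  b <- matrix(spec@backgroundLevel, sh[1], sh[2])
  if (spec@tissueMode == "muscle") {
    stri <- 1 + 0.05 * sin(2 * pi * seq_len(sh[2]) / 60)
    b <- b * matrix(stri, sh[1], sh[2], byrow = TRUE)
  }
  b
}

.addNoise <- function(sig, poissonScale, gaussianSigma) {
  if (is.finite(poissonScale))
    sig[] <- stats::rpois(length(sig), poissonScale * sig) / poissonScale
  if (gaussianSigma > 0)
    sig[] <- sig + stats::rnorm(length(sig), 0, gaussianSigma)
  sig[sig < 0] <- 0
  sig[sig > 65535] <- 65535
  sig
}

#' Simulate one multi-channel field with per-nucleus ground truth
#'
#' Renders DAPI, NPM1, NCL and mHTT channels. Per nucleus, each nucleolar
#' marker is independently in the "nucleolar" state (probability
#' `positiveFraction`: 1-3 compact disk/annulus bodies at `contrast` times
#' the nucleoplasmic mean) or "delocalized" (uniform over the nucleus).
#' With probability `inclusionFraction` the nucleus carries one bright mHTT
#' inclusion whose intensity is set so that the background-subtracted
#' nucleoplasm/inclusion mean ratio equals a truncated-normal draw
#' (`dispersalRatioMean`, `dispersalRatioSd`). Identical spec and seed give
#' bit-identical output.
#'
#' @param spec a [FieldSpec-class].
#' @param seed integer seed (defaults to `spec@seed`).
#' @param fieldId,sampleId identifiers stored in the output.
#' @return List with elements `field` (an [ImageField-class]) and `truth`
#'   (one-row-per-nucleus `data.frame`: center, radius, per-marker state and
#'   nucleolus geometry, rendered nucleolar areas in um^2, inclusion flag and
#'   geometry, `trueDispersalRatio` — `NA` unless `hasInclusion` — and the
#'   per-nucleus NCL intensity multiplier).
#' @examples
#' sim <- simulateField(fieldSpec(nNuclei = 5, seed = 7))
#' nrow(sim$truth)
#' @export
simulateField <- function(spec, seed = spec@seed, fieldId = "field",
                          sampleId = NA_character_) {
  validObject(spec)
  .withSeed(seed, {
    sh <- spec@fieldShape
    pxs <- spec@pixelSize
    n <- spec@nNuclei
    npx <- prod(sh)
    bg <- .backgroundField(spec)
    chans <- c("DAPI", "NPM1", "NCL", "mHTT")
    sig <- array(0, dim = c(sh[1], sh[2], 4),
                 dimnames = list(NULL, NULL, chans))

    emptyTruth <- data.frame(
      fieldId = character(), nucleusId = integer(), centerRow = numeric(),
      centerCol = numeric(), radiusUm = numeric(), aspect = numeric(),
      theta = numeric(), npm1State = character(), nclState = character(),
      npm1Nucleoli = character(), nclNucleoli = character(),
      trueNucleolarAreaNpm1Um2 = numeric(),
      trueNucleolarAreaNclUm2 = numeric(), hasInclusion = logical(),
      inclusionRow = numeric(), inclusionCol = numeric(),
      inclusionRadiusUm = numeric(), trueDispersalRatio = numeric(),
      nclIntensityMult = numeric(), stringsAsFactors = FALSE)

    if (n == 0L) {
      img <- array(0, dim = c(sh[1], sh[2], 4),
                   dimnames = list(NULL, NULL, chans))
      for (k in 1:4)
        img[, , k] <- .addNoise(bg, spec@poissonScale, spec@gaussianSigma)
      fld <- ImageField(img, chans, pxs, fieldId, sampleId)
      return(list(field = fld, truth = emptyTruth))
    }

    pos <- .placeNuclei(spec)
    asp <- spec@nucleusAspect
    aMaj <- pos$radiusPx * sqrt(asp)
    bMin <- pos$radiusPx / sqrt(asp)

    ## per-nucleus states and multipliers
    states <- lapply(spec@markers, function(m)
      stats::runif(n) < m$positiveFraction)
    hasInc <- stats::runif(n) < spec@inclusionFraction
    multD <- pmax(0.3, stats::rnorm(n, 1, spec@cellVariabilityCv))
    multNpm1 <- pmax(0.3, stats::rnorm(n, 1, spec@cellVariabilityCv))
    multMhtt <- pmax(0.3, stats::rnorm(n, 1, spec@cellVariabilityCv))
    ## coupled (NCL multiplier, dispersal ratio) latent pair
    rho <- spec@nclRatioCorrelation
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    multNcl <- pmax(0.3, 1 + 0.15 * z1)
    ratio <- spec@dispersalRatioMean + spec@dispersalRatioSd * z2
    bad <- which(ratio < 0.02)
    while (length(bad)) {  # truncation just above zero
      ratio[bad] <- spec@dispersalRatioMean +
        spec@dispersalRatioSd * stats::rnorm(length(bad))
      bad <- bad[ratio[bad] < 0.02]
    }

    nucIdxList <- vector("list", n)
    nucleoliStr <- list(NPM1 = character(n), NCL = character(n))
    nucArea <- list(NPM1 = numeric(n), NCL = numeric(n))
    incRow <- incCol <- rep(NA_real_, n)

    for (i in seq_len(n)) {
      idx <- .ellipseIdx(sh, pos$row[i], pos$col[i], aMaj[i], bMin[i],
                         pos$theta[i])
      nucIdxList[[i]] <- idx
      sig[idx] <- spec@dapiLevel * multD[i]  # channel 1 (DAPI)

      for (mk in c("NPM1", "NCL")) {
        m <- spec@markers[[mk]]
        off <- (match(mk, chans) - 1L) * npx
        base <- m$nucleoplasmLevel *
          (if (mk == "NPM1") multNpm1[i] else multNcl[i])
        sig[off + idx] <- base
        if (states[[mk]][i]) {
          k <- sample(seq(m$nucleoliRange[1], m$nucleoliRange[2]), 1L)
          rn <- m$nucleolusRadius / pxs
          bodies <- .placeNucleoli(k, pos$row[i], pos$col[i], aMaj[i],
                                   bMin[i], pos$theta[i], rn)
          area <- 0L
          for (j in seq_len(k)) {
            if (m$ringMode == "annulus") {
              ann <- .annulusIdx(sh, bodies[j, 1], bodies[j, 2], rn)
              sig[off + ann$rim] <- m$contrast * base
              sig[off + ann$core] <- m$coreFraction * m$contrast * base
              area <- area + length(ann$all)
            } else {
              d <- .diskIdx(sh, bodies[j, 1], bodies[j, 2], rn)
              sig[off + d] <- m$contrast * base
              area <- area + length(d)
            }
          }
          nucleoliStr[[mk]][i] <- .encodeBodies(bodies)
          nucArea[[mk]][i] <- area * pxs^2
        } else {
          nucleoliStr[[mk]][i] <- ""
        }
      }

      ## mHTT: diffuse nucleoplasmic signal; optional single inclusion
      offM <- 3L * npx
      lvl <- spec@mhttNucleoplasmLevel * multMhtt[i]
      sig[offM + idx] <- lvl
      if (hasInc[i]) {
        ri <- spec@inclusionRadius / pxs
        p <- .placeNucleoli(1L, pos$row[i], pos$col[i], aMaj[i], bMin[i],
                            pos$theta[i], ri)
        di <- .diskIdx(sh, p[1, 1], p[1, 2], ri)
        sig[offM + di] <- lvl / ratio[i]
        incRow[i] <- p[1, 1]; incCol[i] <- p[1, 2]
      }
    }

    img <- array(0, dim = c(sh[1], sh[2], 4),
                 dimnames = list(NULL, NULL, chans))
    for (k in 1:4)
      img[, , k] <- .addNoise(bg + sig[, , k], spec@poissonScale,
                              spec@gaussianSigma)

    truth <- data.frame(
      fieldId = fieldId, nucleusId = seq_len(n), centerRow = pos$row,
      centerCol = pos$col, radiusUm = pos$radiusPx * pxs, aspect = asp,
      theta = pos$theta,
      npm1State = ifelse(states$NPM1, "nucleolar", "delocalized"),
      nclState = ifelse(states$NCL, "nucleolar", "delocalized"),
      npm1Nucleoli = nucleoliStr$NPM1, nclNucleoli = nucleoliStr$NCL,
      trueNucleolarAreaNpm1Um2 = nucArea$NPM1,
      trueNucleolarAreaNclUm2 = nucArea$NCL,
      hasInclusion = hasInc, inclusionRow = incRow, inclusionCol = incCol,
      inclusionRadiusUm = ifelse(hasInc, spec@inclusionRadius, NA_real_),
      trueDispersalRatio = ifelse(hasInc, ratio, NA_real_),
      nclIntensityMult = multNcl, stringsAsFactors = FALSE)

    list(field = ImageField(img, chans, pxs, fieldId, sampleId),
         truth = truth)
  })
}

.subSeed <- function(master, gi, si, fi) {
  as.integer(((master %% 100003) * 1009 + gi * 1000033 + si * 10007 +
                fi * 101) %% 2147483587) + 1L
}

#' Plan a hierarchical cohort (group -> sample -> field)
#'
#' Builds the manifest that maps every field to its sample and group and
#' assigns each field a deterministic sub-seed derived from the master seed
#' and the (group, sample, field) indices only — so changing one group's
#' parameters never perturbs another group's rasters.
#'
#' @param groupSpecs named list of [FieldSpec-class], one per group.
#' @param samplesPerGroup integer scalar or per-group vector.
#' @param fieldsPerSample integer scalar or per-group vector.
#' @param seed master integer seed.
#' @return `data.frame` with columns `group`, `sampleId`, `fieldId`,
#'   `fieldIndex`, `seed`.
#' @export
cohortManifest <- function(groupSpecs, samplesPerGroup, fieldsPerSample,
                           seed) {
  gn <- names(groupSpecs)
  if (is.null(gn) || any(!nzchar(gn)) || anyDuplicated(gn))
    stop("groupSpecs must be a uniquely named list (duplicate or empty group names)")
  if (length(groupSpecs) < 1L) stop("need at least one group")
  nS <- rep_len(as.integer(samplesPerGroup), length(gn))
  nF <- rep_len(as.integer(fieldsPerSample), length(gn))
  if (any(nS < 1L) || any(nF < 1L))
    stop("each group needs at least one sample and one field")
  rows <- list()
  for (gi in seq_along(gn)) {
    for (si in seq_len(nS[gi])) {
      for (fi in seq_len(nF[gi])) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = gn[gi],
          sampleId = sprintf("%s_s%02d", gn[gi], si),
          fieldId = sprintf("%s_s%02d_f%02d", gn[gi], si, fi),
          fieldIndex = fi, seed = .subSeed(seed, gi, si, fi),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a cohort of fields
#'
#' Mirrors an N-animals-by-fields acquisition design. Each field is
#' simulated with [simulateField()] under its manifest sub-seed.
#'
#' @inheritParams cohortManifest
#' @param keepFields if `FALSE`, rasters are dropped and only truth +
#'   manifest are returned (memory-friendly for large cohorts).
#' @return List with `fields` (named list of [ImageField-class], or `NULL`),
#'   `truth` (row-bound ground truth with `group`/`sampleId` joined) and
#'   `manifest`.
#' @examples
#' gs <- list(ctrl = fieldSpec(nNuclei = 5), mut = fieldSpec(nNuclei = 5))
#' coh <- simulateCohort(gs, samplesPerGroup = 1, fieldsPerSample = 1, seed = 1)
#' names(coh$fields)
#' @export
simulateCohort <- function(groupSpecs, samplesPerGroup, fieldsPerSample,
                           seed, keepFields = TRUE) {
  man <- cohortManifest(groupSpecs, samplesPerGroup, fieldsPerSample, seed)
  fields <- if (keepFields) vector("list", nrow(man)) else NULL
  truths <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sp <- groupSpecs[[man$group[i]]]
    sim <- simulateField(sp, seed = man$seed[i], fieldId = man$fieldId[i],
                         sampleId = man$sampleId[i])
    if (keepFields) fields[[i]] <- sim$field
    tt <- sim$truth
    tt$group <- rep_len(man$group[i], nrow(tt))
    tt$sampleId <- rep_len(man$sampleId[i], nrow(tt))
    truths[[i]] <- tt
  }
  if (keepFields) names(fields) <- man$fieldId
  list(fields = fields, truth = do.call(rbind, truths), manifest = man)
}
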