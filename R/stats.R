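## Nonparametric testing layer on per-sample values, plus the two tabular
## formulas (delta-delta-Ct relative expression, disease-burden score).
## Per-sample means are the statistical unit: per-nucleus measurements are
## aggregated with summarizeBySample() before any test.

.newComparison <- function(measure, test, groups, statistic, p,
                           pairwise = data.frame(), relDiff = NA_real_) {
  means <- vapply(groups, mean, numeric(1))
  sems <- vapply(groups, .sem, numeric(1))
  new("ComparisonResult", measure = measure, test = test, groups = groups,
      statistic = statistic, p = p, pairwise = pairwise,
      groupMeans = means, groupSEM = sems, relDiff = relDiff)
}

## exact permutation distribution of the rank-sum of group A (mid-ranks)
.mwuExactP <- function(rk, n1) {
  N <- length(rk)
  idx <- utils::combn(N, n1)
  u <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  uObs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  pl <- mean(u <= uObs + eps)
  pg <- mean(u >= uObs - eps)
  min(1, 2 * min(pl, pg))
}

#' Mann-Whitney U test (two-tailed)
#'
#' Nonparametric unpaired two-group comparison of per-sample values. For a
#' combined sample size up to `exactMax` (default 16) the two-tailed p-value
#' is exact, from full enumeration of the permutation distribution of the
#' rank sum (ties handled by mid-ranks). Larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric per-sample values of the two groups (each >= 2).
#' @param measure label stored in the result.
#' @param groupNames names of the two groups.
#' @param exactMax switch point between exact and approximate p.
#' @return A [ComparisonResult-class]; `statistic` carries `U` (of the
#'   first group) and the relative difference is `100 * (1 - mean(y)/mean(x))`.
#' @examples
#' res <- mwuTest(c(1, 2, 3), c(4, 5, 6))
#' pValue(res)  # exact: 0.1
#' @export
mwuTest <- function(x, y, measure = "value",
                    groupNames = c("A", "B"), exactMax = 16L) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values for the Mann-Whitney U test")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- if (N <= exactMax) {
    .mwuExactP(rk, n1)
  } else {
    ties <- table(rk)
    tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieCorr)
    mu <- n1 * n2 / 2
    z <- u1 - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    min(1, 2 * stats::pnorm(-abs(z)))
  }
  groups <- stats::setNames(list(x, y), groupNames)
  relDiff <- 100 * (1 - mean(y) / mean(x))
  .newComparison(measure, "MWU", groups, c(U = u1), p, relDiff = relDiff)
}

#' Kruskal-Wallis test with Dunn's post hoc contrasts
#'
#' Tie-corrected Kruskal-Wallis H across three or more groups, followed by
#' Dunn's z-tests on mean ranks for every pair, with Bonferroni family-wise
#' adjustment over all pairwise contrasts. When all values are identical
#' the convention H = 0, p = 1 applies.
#'
#' @param groups named list (>= 3) of numeric per-sample vectors (each >= 2).
#' @param measure label stored in the result.
#' @param adjust p-adjustment method for the pairwise contrasts (a
#'   `p.adjust` method name; default `"bonferroni"`).
#' @return A [ComparisonResult-class]; `pairwiseTable()` gives one row per
#'   contrast with `z`, raw `p` and adjusted `pAdj`.
#' @export
kruskalDunn <- function(groups, measure = "value", adjust = "bonferroni") {
  if (length(groups) < 3L)
    stop("kruskalDunn needs at least 3 groups (use mwuTest for 2)")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, 1L)),
                levels = names(groups))
  N <- length(vals)
  pairs <- utils::combn(names(groups), 2)
  if (stats::var(vals) == 0) {
    pw <- data.frame(groupA = pairs[1, ], groupB = pairs[2, ], z = 0,
                     p = 1, pAdj = 1, stringsAsFactors = FALSE)
    return(.newComparison(measure, "KW_Dunn", groups, c(H = 0), 1, pw))
  }
  kw <- stats::kruskal.test(vals, grp)
  rk <- rank(vals)
  meanRank <- tapply(rk, grp, mean)
  nPer <- tabulate(grp)
  ties <- table(rk)
  tieSum <- sum(ties^3 - ties) / (12 * (N - 1))
  varBase <- N * (N + 1) / 12 - tieSum
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- match(pairs[1, j], names(groups))
    b <- match(pairs[2, j], names(groups))
    se <- sqrt(varBase * (1 / nPer[a] + 1 / nPer[b]))
    z[j] <- (meanRank[a] - meanRank[b]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  pw <- data.frame(groupA = pairs[1, ], groupB = pairs[2, ], z = z, p = p,
                   pAdj = pmin(1, stats::p.adjust(p, method = adjust)),
                   stringsAsFactors = FALSE)
  .newComparison(measure, "KW_Dunn", groups,
                 c(H = unname(kw$statistic)), max(kw$p.value, 1e-300), pw)
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param measure label stored in the result.
#' @return A [ComparisonResult-class]; `statistic["r"]` is the sample
#'   correlation.
#' @export
pearsonR <- function(x, y, measure = "correlation") {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  .newComparison(measure, "Pearson", list(x = x, y = y),
                 c(r = unname(ct$estimate), t = unname(ct$statistic)),
                 max(ct$p.value, 1e-300))
}

#' Relative qPCR expression (delta-delta-Ct)
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`; the fold change is
#' `2^-(dCt - mean dCt over the control group)`, i.e. expression relative
#' to the mean of the control samples.
#'
#' @param ct `data.frame` with columns `sample`, `group`, `gene`, `ct`.
#' @param targetGene gene of interest (e.g. a 47S pre-rRNA amplicon).
#' @param referenceGene stably expressed reference gene (e.g. `Gapdh`,
#'   `Hprt` for striatum, `Metap1` for muscle).
#' @param controlGroup name of the control group.
#' @return `data.frame(sample, group, deltaCt, foldChange)`, one row per
#'   sample.
#' @examples
#' ct <- data.frame(sample = rep(c("c1", "c2", "m1"), each = 2),
#'                  group = rep(c("ctrl", "ctrl", "mut"), each = 2),
#'                  gene = rep(c("47S", "Gapdh"), 3),
#'                  ct = c(25, 20, 25, 20, 26, 20))
#' relativeExpression(ct, "47S", "Gapdh", "ctrl")  # mutant fold 0.5
#' @export
relativeExpression <- function(ct, targetGene, referenceGene, controlGroup) {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table must have columns ", paste(need, collapse = ", "))
  if (any(ct$ct <= 0)) stop("Ct values must be > 0")
  samples <- unique(ct[, c("sample", "group")])
  dCt <- vapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample[i]
    tg <- ct$ct[ct$sample == s & ct$gene == targetGene]
    rf <- ct$ct[ct$sample == s & ct$gene == referenceGene]
    if (length(tg) != 1L)
      stop("sample '", s, "': expected one Ct for target '", targetGene, "'")
    if (length(rf) != 1L)
      stop("sample '", s, "': missing reference gene '", referenceGene, "' Ct")
    tg - rf
  }, numeric(1))
  isCtrl <- samples$group == controlGroup
  if (!any(isCtrl)) stop("control group '", controlGroup, "' not found")
  fold <- 2^-(dCt - mean(dCt[isCtrl]))
  data.frame(sample = samples$sample, group = samples$group, deltaCt = dCt,
             foldChange = fold, stringsAsFactors = FALSE)
}

#' Disease-burden score for HTT CAG-repeat carriers
#'
#' `DBS = (CAG - 35.5) * age`, a cumulative mutation-exposure index;
#' carriers are screening-eligible at DBS >= 250.
#'
#' @param cag CAG repeat length(s) (> 0).
#' @param age age(s) in years (> 0).
#' @return `data.frame(CAG, age, DBS, screenEligible)`.
#' @examples
#' diseaseBurden(43, 50)  # DBS 375, eligible
#' @export
diseaseBurden <- function(cag, age) {
  if (any(cag <= 0) || any(age <= 0)) stop("CAG and age must be > 0")
  dbs <- (cag - 35.5) * age
  data.frame(CAG = cag, age = age, DBS = dbs, screenEligible = dbs >= 250)
}

#' Compare per-sample summaries between groups
#'
#' Dispatches on the number of groups: two groups go to [mwuTest()], three
#' or more to [kruskalDunn()].
#'
#' @param sampleSummary `data.frame(group, sampleId, value)` as produced by
#'   [summarizeBySample()] and friends.
#' @param measure label stored in the result.
#' @return A [ComparisonResult-class].
#' @export
compareGroups <- function(sampleSummary, measure = "value") {
  ss <- sampleSummary[!is.na(sampleSummary$value), ]
  groups <- split(ss$value, ss$group)
  groups <- groups[order(match(names(groups), unique(ss$group)))]
  if (length(groups) < 2L) stop("need at least two groups to compare")
  if (length(groups) == 2L)
    mwuTest(groups[[1]], groups[[2]], measure = measure,
            groupNames = names(groups))
  else kruskalDunn(groups, measure = measure)
}

#' @rdname pValue
#' @export
setMethod("pValue", "ComparisonResult", function(x) x@p)

#' @rdname pairwiseTable
#' @export
setMethod("pairwiseTable", "ComparisonResult", function(x) x@pairwise)

#' @rdname relativeDifference
#' @export
setMethod("relativeDifference", "ComparisonResult", function(x) x@relDiff)

#' @rdname groupValues
#' @export
setMethod("groupValues", "ComparisonResult", function(x) x@groups)

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult [", object@test, "] on '", object@measure, "'\n",
      sep = "")
  for (g in names(object@groups))
    cat(sprintf("  %s: n=%d, mean=%.4g +/- %.3g (SEM)\n", g,
                length(object@groups[[g]]), object@groupMeans[g],
                object@groupSEM[g]))
  st <- paste(names(object@statistic),
              signif(object@statistic, 4), sep = "=", collapse = ", ")
  cat("  ", st, ", p = ", signif(object@p, 3), "\n", sep = "")
  if (!is.na(object@relDiff))
    cat(sprintf("  relative difference: %.1f%%\n", object@relDiff))
  if (nrow(object@pairwise)) {
    cat("  Dunn pairwise (adjusted):\n")
    for (j in seq_len(nrow(object@pairwise)))
      cat(sprintf("    %s vs %s: z=%.3f, pAdj=%.4g\n",
                  object@pairwise$groupA[j], object@pairwise$groupB[j],
                  object@pairwise$z[j], object@pairwise$pAdj[j]))
  }
})
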