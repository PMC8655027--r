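.mhttFixture <- function(npLevel, incLevel, sh = c(96L, 96L), r = 30,
                         rInc = 6) {
  nuc <- diskMask(sh, 48, 48, r)
  inc <- diskMask(sh, 40, 48, rInc)
  img <- matrix(0, sh[1], sh[2])
  img[nuc] <- npLevel
  img[inc] <- incLevel
  list(field = makeField(list(DAPI = matrix(0, sh[1], sh[2]) + 5000 * nuc,
                              mHTT = img)),
       nuclei = makeNucleusSet(list(nuc)), incMask = inc)
}

test_that("uniform mHTT yields no inclusion and an NA ratio", {
  fx <- .mhttFixture(npLevel = 80, incLevel = 80)
  res <- detectInclusions(fx$field, fx$nuclei)
  expect_false(res$hasInclusion)
  expect_true(is.na(res$dispersalRatio))
})

test_that("forced arithmetic: nucleoplasm 80 over inclusion 200 gives ratio 0.40", {
  fx <- .mhttFixture(npLevel = 80, incLevel = 200)
  res <- detectInclusions(fx$field, fx$nuclei)
  expect_true(res$hasInclusion)
  expect_equal(res$nInclusions, 1L)
  expect_equal(res$dispersalRatio, 0.40, tolerance = 0.02)
  expect_equal(res$dispersalRatio, res$nucleoplasmMean / res$inclusionMean)
  # count and area match the constructed truth exactly (noise-free)
  expect_equal(res$inclusionAreaUm2, sum(fx$incMask) * 0.1^2)
})

test_that("the dispersal ratio is gain-invariant", {
  fx <- .mhttFixture(npLevel = 80, incLevel = 200)
  r1 <- detectInclusions(fx$field, fx$nuclei)
  scaled <- fx$field
  scaled@imageData <- fx$field@imageData * 3.7
  r2 <- detectInclusions(scaled, fx$nuclei)
  expect_equal(r1$dispersalRatio, r2$dispersalRatio, tolerance = 1e-6)
})

test_that("per-sample dispersal ratio and prevalence recover generator truth", {
  gs <- list(g = fieldSpec(nNuclei = 40, fieldShape = c(640L, 640L),
                           inclusionFraction = 1, dispersalRatioMean = 0.4,
                           dispersalRatioSd = 0.1))
  man <- cohortManifest(gs, 1, 4, seed = 23)
  meas <- truthRatio <- list()
  for (i in seq_len(nrow(man))) {
    sim <- simulateField(gs$g, seed = man$seed[i], fieldId = man$fieldId[i])
    ns <- segmentNuclei(sim$field)
    meas[[i]] <- detectInclusions(sim$field, ns)
    truthRatio[[i]] <- sim$truth$trueDispersalRatio
  }
  est <- dispersalRatioSummary(do.call(rbind, meas), man)
  expect_lt(abs(est$value / mean(unlist(truthRatio)) - 1), 0.05)
  prev <- inclusionPrevalence(do.call(rbind, meas), man)
  expect_gt(prev$value, 0.95)
})

test_that("inclusion prevalence aggregates like the other per-nucleus flags", {
  meas <- data.frame(fieldId = "f", hasInclusion = rep(c(TRUE, FALSE), 4),
                     valid = TRUE)
  expect_equal(inclusionPrevalence(meas)$value, 0.5)
  none <- data.frame(fieldId = "f", hasInclusion = rep(FALSE, 5),
                     valid = TRUE)
  expect_equal(inclusionPrevalence(none)$value, 0)
})

test_that("NCL intensity couples to the dispersal ratio at the simulated correlation", {
  # NCL delocalized everywhere: the coupling acts on the diffuse nuclear
  # intensity, so the whole-nucleus mean is the clean coupled readout
  gs <- list(g = fieldSpec(nNuclei = 84, fieldShape = c(1024L, 1024L),
                           inclusionFraction = 1, nclRatioCorrelation = 0.67,
                           markers = list(NCL = list(positiveFraction = 0))))
  man <- cohortManifest(gs, 1, 4, seed = 29)
  pairs <- list()
  for (i in seq_len(nrow(man))) {
    sim <- simulateField(gs$g, seed = man$seed[i], fieldId = man$fieldId[i])
    ns <- segmentNuclei(sim$field)
    ncl <- scoreNucleolus(sim$field, ns, "NCL")
    inc <- detectInclusions(sim$field, ns)
    ok <- inc$hasInclusion & inc$valid & !ncl$skipped
    pairs[[i]] <- data.frame(x = ncl$nuclearMeanIntensity[ok],
                             y = inc$dispersalRatio[ok])
  }
  d <- do.call(rbind, pairs)
  d <- d[seq_len(min(nrow(d), 335)), ]
  res <- pearsonR(d$x, d$y)
  expect_gte(nrow(d), 300)
  expect_lt(abs(res@statistic[["r"]] - 0.67), 0.07)
})

test_that("line scans profile and normalize channels correctly", {
  sh <- c(96L, 96L)
  flat <- matrix(500, sh[1], sh[2])
  ann <- matrix(100, sh[1], sh[2])
  ann[diskMask(sh, 48, 48, 10) & !diskMask(sh, 48, 48, 5)] <- 1000
  disk <- matrix(100, sh[1], sh[2])
  disk[diskMask(sh, 48, 48, 8)] <- 900
  f <- makeField(list(FLAT = flat, ANN = ann, DISK = disk))
  ls <- lineScan(f, c(48, 20), c(48, 76))
  expect_true(all(diff(ls$positionUm) > 0))
  expect_true(all(abs(ls$FLAT - 1) < 1e-9))  # constant channel -> flat 1.0
  # annulus: two local maxima symmetric about the midpoint
  peaks <- which(ls$ANN > 0.99)
  mid <- mean(range(ls$positionUm))
  expect_gt(max(diff(peaks)), 5)  # two separated plateaus
  expect_lt(abs(mean(ls$positionUm[peaks]) - mid), 0.2)
  # disk: one central plateau
  dp <- which(ls$DISK > 0.99)
  expect_equal(max(diff(dp)), 1L)
  expect_error(lineScan(f, c(10, 10), c(10, 10)), "zero-length")
})
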