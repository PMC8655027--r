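# fixtures: one round nucleus, marker rendered by hand, zero background

.nucleusFixture <- function(markerFun, sh = c(96L, 96L), r = 30) {
  nuc <- diskMask(sh, 48, 48, r)
  marker <- matrix(0, sh[1], sh[2])
  marker[nuc] <- 1000
  marker <- markerFun(marker, nuc)
  list(field = makeField(list(DAPI = matrix(0, sh[1], sh[2]) + 5000 * nuc,
                              NPM1 = marker)),
       nuclei = makeNucleusSet(list(nuc)))
}

test_that("uniform marker signal is called delocalized (negative)", {
  fx <- .nucleusFixture(function(m, nuc) m)
  sc <- scoreNucleolus(fx$field, fx$nuclei, "NPM1")
  expect_false(sc$positive)
  expect_equal(sc$nucleolarAreaUm2, 0)
  expect_true(is.na(sc$ringScore))
})

test_that("an annulus at 3x contrast is positive with a positive ring score", {
  rn <- 8  # 0.8 um at 0.1 um/px
  fx <- .nucleusFixture(function(m, nuc) {
    ann <- diskMask(dim(m), 48, 48, rn) & !diskMask(dim(m), 48, 48, 0.55 * rn)
    core <- diskMask(dim(m), 48, 48, 0.55 * rn)
    m[ann] <- 3000
    m[core] <- 0.4 * 3000
    m
  })
  sc <- scoreNucleolus(fx$field, fx$nuclei, "NPM1")
  expect_true(sc$positive)
  expect_gt(sc$ringScore, 0)
  expect_lt(abs(sc$nucleolarAreaUm2 / (pi * 0.8^2) - 1), 0.15)
})

test_that("a filled disk at 3x contrast is positive with non-positive ring score", {
  fx <- .nucleusFixture(function(m, nuc) {
    m[diskMask(dim(m), 48, 48, 8)] <- 3000
    m
  })
  sc <- scoreNucleolus(fx$field, fx$nuclei, "NPM1")
  expect_true(sc$positive)
  expect_lte(sc$ringScore, 0 + 1e-9)
  expect_equal(sc$nNucleoli, 1L)
})

test_that("ring score separates annulus from disk on generator fields, noise-free", {
  for (mode in c("annulus", "disk")) {
    sp <- fieldSpec(nNuclei = 8, fieldShape = c(256L, 256L), seed = 31,
                    nucleusRadius = c(2.6, 0.15),
                    poissonScale = Inf, gaussianSigma = 0,
                    markers = list(NPM1 = list(positiveFraction = 1,
                                               ringMode = mode)))
    sim <- simulateField(sp)
    ns <- segmentNuclei(sim$field)
    sc <- scoreNucleolus(sim$field, ns, "NPM1")
    sc <- sc[sc$positive, ]
    expect_gt(nrow(sc), 3)
    if (mode == "annulus") expect_true(all(sc$ringScore > 0))
    else expect_true(all(sc$ringScore <= 1e-9))
  }
})

test_that("positive fractions aggregate per field then per sample", {
  meas <- data.frame(fieldId = rep(c("f1", "f2"), c(10, 10)),
                     positive = c(rep(c(TRUE, FALSE), c(3, 7)),
                                  rep(c(TRUE, FALSE), c(4, 6))))
  perField <- fractionPositive(meas)
  expect_equal(perField$value[perField$fieldId == "f1"], 0.30)
  man <- data.frame(group = "g", sampleId = "s1", fieldId = c("f1", "f2"))
  # fields at 0.3 and 0.4 average to 0.35; and 0.2/0.4 to 0.30
  expect_equal(fractionPositive(meas, man)$value, 0.35)
  meas$positive[1:10] <- rep(c(TRUE, FALSE), c(2, 8))
  expect_equal(fractionPositive(meas, man)$value, 0.30)
})

test_that("nucleolar area per DAPI nucleus counts negatives as zero", {
  meas <- data.frame(fieldId = "f1", positive = c(TRUE, TRUE, FALSE),
                     nucleolarAreaUm2 = c(3, 2, 0))
  expect_equal(nucleolarAreaPerNucleus(meas)$value, 5 / 3, tolerance = 1e-6)
  expect_equal(nucleolarAreaPerNucleus(meas, over = "positives")$value, 2.5)
  one <- data.frame(fieldId = "f1", positive = TRUE,
                    nucleolarAreaUm2 = 300 * 0.1^2)
  expect_equal(nucleolarAreaPerNucleus(one)$value, 3.0)
})

test_that("markers are scored independently: swapping channels swaps outputs", {
  sp <- fieldSpec(nNuclei = 10, fieldShape = c(256L, 256L), seed = 17,
                  nucleusRadius = c(2.6, 0.15),
                  markers = list(NPM1 = list(positiveFraction = 0.8),
                                 NCL = list(positiveFraction = 0.2)))
  sim <- simulateField(sp)
  ns <- segmentNuclei(sim$field)
  expect_gt(length(ns), 5)
  a1 <- scoreNucleolus(sim$field, ns, "NPM1")
  a2 <- scoreNucleolus(sim$field, ns, "NCL")
  swapped <- sim$field
  swapped@imageData[, , "NPM1"] <- sim$field@imageData[, , "NCL"]
  swapped@imageData[, , "NCL"] <- sim$field@imageData[, , "NPM1"]
  b1 <- scoreNucleolus(swapped, ns, "NPM1")
  b2 <- scoreNucleolus(swapped, ns, "NCL")
  dropMarker <- function(d) d[setdiff(names(d), "marker")]
  expect_identical(dropMarker(a1), dropMarker(b2))
  expect_identical(dropMarker(a2), dropMarker(b1))
})

test_that("positive-fraction recovery is within 0.05 at ~200 nuclei per sample", {
  gs <- list(g = fieldSpec(nNuclei = 30, seed = 1,
                           markers = list(NPM1 = list(positiveFraction = 0.6))))
  man <- cohortManifest(gs, samplesPerGroup = 1, fieldsPerSample = 7,
                        seed = 3)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    sim <- simulateField(gs$g, seed = man$seed[i], fieldId = man$fieldId[i])
    ns <- segmentNuclei(sim$field)
    scoreNucleolus(sim$field, ns, "NPM1")
  })
  est <- fractionPositive(do.call(rbind, rows), man)
  expect_gte(sum(est$nNuclei), 150)
  expect_lt(abs(est$value - 0.6), 0.05)
})
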