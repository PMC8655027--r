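test_that("empty spec gives background-only channels and empty truth", {
  sp <- fieldSpec(nNuclei = 0, fieldShape = c(64L, 64L), seed = 1)
  sim <- simulateField(sp)
  expect_equal(nrow(sim$truth), 0L)
  dapi <- getChannel(sim$field, "DAPI")
  # background 200 with shot + read noise, no structure
  expect_lt(abs(mean(dapi) - 200), 15)
  expect_lt(max(dapi), 200 + 10 * (sqrt(200 / 0.1) * 0.1 + 20))
})

test_that("identical spec and seed reproduce rasters and truth bit for bit", {
  sp <- fieldSpec(nNuclei = 8, fieldShape = c(128L, 128L), seed = 42,
                  nucleusRadius = c(1.2, 0.1), inclusionFraction = 0.5)
  a <- simulateField(sp)
  b <- simulateField(sp)
  expect_identical(a$field@imageData, b$field@imageData)
  expect_identical(a$truth, b$truth)
})

test_that("nucleolar state draws follow the Bernoulli fraction across seeds", {
  # small nuclei in a small field keep 200 replicate draws cheap
  nPos <- vapply(1:200, function(s) {
    sp <- fieldSpec(nNuclei = 50, fieldShape = c(192L, 192L),
                    nucleusRadius = c(0.8, 0.05), seed = s,
                    markers = list(NPM1 = list(positiveFraction = 0.6,
                                               nucleolusRadius = 0.25)))
    sum(simulateField(sp)$truth$npm1State == "nucleolar")
  }, numeric(1))
  se <- sqrt(0.6 * 0.4 / (50 * 200))
  expect_lt(abs(mean(nPos) / 50 - 0.6), 3 * se)
  # per-field counts look Binomial(50, 0.6): variance in a sane band
  expect_gt(var(nPos), 0.5 * 50 * 0.6 * 0.4)
  expect_lt(var(nPos), 1.7 * 50 * 0.6 * 0.4)
})

test_that("infeasible density fails with an error naming the density", {
  sp <- fieldSpec(nNuclei = 60, fieldShape = c(96L, 96L), seed = 1,
                  maxPlacementRetries = 25L)
  expect_error(simulateField(sp), "density")
})

test_that("invalid spec values are rejected with the offending field named", {
  expect_error(fieldSpec(inclusionFraction = 1.4), "inclusionFraction")
  expect_error(fieldSpec(pixelSize = -1), "pixelSize")
  expect_error(fieldSpec(markers = list(NPM1 = list(positiveFraction = 2))),
               "positiveFraction")
})

test_that("noise-free render reproduces the true dispersal ratio within 1%", {
  sp <- fieldSpec(nNuclei = 12, fieldShape = c(256L, 256L), seed = 9,
                  nucleusRadius = c(1.8, 0.1), inclusionFraction = 1,
                  poissonScale = Inf, gaussianSigma = 0)
  sim <- simulateField(sp)
  img <- getChannel(sim$field, "mHTT")
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$truth[i, ]
    nuc <- truthNucleusMask(row, dim(img), 0.1)
    inc <- diskMask(dim(img), row$inclusionRow, row$inclusionCol,
                    row$inclusionRadiusUm / 0.1)
    np <- nuc & !inc
    measured <- (mean(img[np]) - 200) / (mean(img[inc & nuc]) - 200)
    expect_lt(abs(measured / row$trueDispersalRatio - 1), 0.01)
  }
})

test_that("true nucleolar area matches pi r^2 within pixelization error", {
  sp <- fieldSpec(nNuclei = 15, fieldShape = c(256L, 256L), seed = 5,
                  nucleusRadius = c(1.8, 0.1),
                  markers = list(NCL = list(positiveFraction = 1,
                                            nucleoliRange = c(1L, 1L),
                                            nucleolusRadius = 0.8)))
  tr <- simulateField(sp)$truth
  rPx <- 0.8 / 0.1
  analytic <- pi * 0.8^2
  tol <- 2 * (2 * pi * rPx) * 0.1^2  # two pixel rows of perimeter
  expect_true(all(abs(tr$trueNucleolarAreaNclUm2 - analytic) <= tol))
})

test_that("cohorts have the right shape and per-field seeds", {
  gs <- list(ctrl = fieldSpec(nNuclei = 3, fieldShape = c(96L, 96L),
                              nucleusRadius = c(1.2, 0.1)),
             mut = fieldSpec(nNuclei = 3, fieldShape = c(96L, 96L),
                             nucleusRadius = c(1.2, 0.1)))
  coh <- simulateCohort(gs, samplesPerGroup = 4, fieldsPerSample = 3,
                        seed = 7)
  expect_length(coh$fields, 24L)
  expect_equal(nrow(coh$manifest), 24L)
  expect_equal(length(unique(coh$manifest$sampleId)), 8L)
  small <- simulateCohort(gs, samplesPerGroup = 1, fieldsPerSample = 1,
                          seed = 7)
  expect_length(small$fields, 2L)
  expect_error(cohortManifest(list(a = gs[[1]], a = gs[[2]]), 1, 1, 1),
               "duplicate|named")
})

test_that("changing one group's parameters leaves the other group's rasters unchanged", {
  gs1 <- list(ctrl = fieldSpec(nNuclei = 4, fieldShape = c(96L, 96L),
                               nucleusRadius = c(1.2, 0.1)),
              mut = fieldSpec(nNuclei = 4, fieldShape = c(96L, 96L),
                              nucleusRadius = c(1.2, 0.1)))
  gs2 <- gs1
  gs2$mut <- updateSpec(gs2$mut, nNuclei = 8L,
                        markers = list(NPM1 = list(positiveFraction = 0.1)))
  a <- simulateCohort(gs1, 2, 2, seed = 11)
  b <- simulateCohort(gs2, 2, 2, seed = 11)
  ctrlIds <- a$manifest$fieldId[a$manifest$group == "ctrl"]
  for (id in ctrlIds)
    expect_identical(a$fields[[id]]@imageData, b$fields[[id]]@imageData)
  mutIds <- a$manifest$fieldId[a$manifest$group == "mut"]
  expect_false(identical(a$fields[[mutIds[1]]]@imageData,
                         b$fields[[mutIds[1]]]@imageData))
})
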