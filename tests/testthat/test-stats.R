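test_that("exact MWU matches frozen enumeration values", {
  res <- mwuTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res@statistic["U"]), 0)
  expect_equal(pValue(res), 0.100)  # 2/20 rank arrangements as extreme
  expect_equal(pValue(mwuTest(c(2, 7, 1), c(2, 7, 1))), 1.0)
  expect_equal(relativeDifference(mwuTest(c(2, 2), c(1, 1))), 50)
})

test_that("exact MWU equals the brute-force permutation oracle (n <= 10, with ties)", {
  set.seed(101)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    # mix of continuous and tie-heavy data
    x <- if (rep %% 2) rnorm(n1) else sample(1:3, n1, replace = TRUE)
    y <- if (rep %% 2) rnorm(n2) else sample(1:3, n2, replace = TRUE)
    expect_equal(pValue(mwuTest(x, y)), mwuOracle(x, y),
                 info = paste("rep", rep))
  }
})

test_that("tie-free exact MWU agrees with wilcox.test", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(5)
    y <- rnorm(6)
    expect_equal(pValue(mwuTest(x, y)),
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("large-sample MWU uses the tie-corrected normal approximation", {
  set.seed(11)
  x <- round(rnorm(12), 1)
  y <- round(rnorm(10, 0.5), 1)
  expect_equal(pValue(mwuTest(x, y)),
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("MWU holds its type-I error near the nominal 5% level", {
  set.seed(2024)
  rejections <- mean(vapply(seq_len(5000), function(i) {
    pValue(mwuTest(rnorm(6), rnorm(6))) < 0.05
  }, logical(1)))
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
})

test_that("Kruskal-Wallis H matches hand computation and kruskal.test", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  res <- kruskalDunn(g)
  # ranks 1..6; H = 12/42 * 2 * ((1.5-3.5)^2 + 0 + (5.5-3.5)^2)
  expect_equal(unname(res@statistic["H"]), 32 / 7, tolerance = 1e-9)
  expect_equal(unname(res@statistic["H"]), kwOracle(g), tolerance = 1e-9)
  set.seed(3)
  g2 <- list(a = sample(1:4, 4, TRUE), b = rnorm(5), c = rnorm(3), d = 1:4)
  res2 <- kruskalDunn(g2)
  expect_equal(unname(res2@statistic["H"]), kwOracle(g2), tolerance = 1e-9)
  expect_equal(pValue(res2),
               kruskal.test(unlist(g2),
                            rep(seq_along(g2), lengths(g2)))$p.value)
})

test_that("identical groups give H = 0 and p = 1 by convention", {
  res <- kruskalDunn(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(unname(res@statistic["H"]), 0)
  expect_equal(pValue(res), 1)
})

test_that("Dunn adjusted p-values dominate raw p-values", {
  set.seed(5)
  for (rep in 1:5) {
    g <- list(a = rnorm(4), b = rnorm(3, 1), c = rnorm(5), d = rnorm(3))
    pw <- pairwiseTable(kruskalDunn(g))
    expect_true(all(pw$pAdj >= pw$p - 1e-12))
    expect_true(all(pw$pAdj <= 1))
  }
})

test_that("Pearson r matches the closed-form and is symmetric and affine-invariant", {
  expect_equal(unname(pearsonR(1:5, 1:5)@statistic["r"]), 1)
  expect_equal(unname(pearsonR(1:5, -(1:5))@statistic["r"]), -1)
  r <- pearsonR(c(1, 2, 3), c(2, 1, 4))
  expect_equal(unname(r@statistic["r"]), 0.6547, tolerance = 1e-4)
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(unname(pearsonR(x, y)@statistic["r"]),
               unname(pearsonR(y, x)@statistic["r"]))
  expect_equal(unname(pearsonR(2 * x + 5, y)@statistic["r"]),
               unname(pearsonR(x, y)@statistic["r"]), tolerance = 1e-12)
})

test_that("relative expression reproduces a spreadsheet-style recomputation", {
  ct <- data.frame(
    sample = rep(c("c1", "c2", "c3", "m1", "m2"), each = 2),
    group = rep(c("ctrl", "ctrl", "ctrl", "mut", "mut"), each = 2),
    gene = rep(c("pre47S", "Gapdh"), 5),
    ct = c(24.1, 19.8, 24.9, 20.1, 24.4, 20.0, 25.9, 19.9, 26.3, 20.2))
  res <- relativeExpression(ct, "pre47S", "Gapdh", "ctrl")
  # independent recomputation, wide layout
  dct <- c(24.1 - 19.8, 24.9 - 20.1, 24.4 - 20.0, 25.9 - 19.9, 26.3 - 20.2)
  expect_equal(res$foldChange, 2^-(dct - mean(dct[1:3])))
  # a sample at the control-mean dCt has fold exactly 1; +1 cycle halves it
  expect_equal(relativeExpression(
    data.frame(sample = rep(c("a", "b"), each = 2),
               group = c("ctrl", "ctrl", "mut", "mut"),
               gene = rep(c("t", "r"), 2), ct = c(25, 20, 26, 20)),
    "t", "r", "ctrl")$foldChange, c(1, 0.5))
  bad <- ct[ct$gene != "Gapdh" | ct$sample != "m2", ]
  expect_error(relativeExpression(bad, "pre47S", "Gapdh", "ctrl"), "m2")
})

test_that("disease-burden score and screening flag follow (CAG - 35.5) x age", {
  res <- diseaseBurden(c(35.5, 43, 40), c(63, 50, 40))
  expect_equal(res$DBS, c(0, 375, 180))
  expect_equal(res$screenEligible, c(FALSE, TRUE, FALSE))
  expect_error(diseaseBurden(-1, 40))
  expect_error(diseaseBurden(40, 0))
})

test_that("tests operate on per-sample means: splitting fields changes nothing", {
  vals <- c(0.2, 0.4, 0.3, 0.5, 0.25, 0.45)
  onefield <- data.frame(
    fieldId = rep(sprintf("s%d_f1", 1:3), each = 2),
    positive = rep(c(TRUE, FALSE), 3))
  man1 <- data.frame(group = "g", sampleId = sprintf("s%d", 1:3),
                     fieldId = sprintf("s%d_f1", 1:3))
  # same nuclei split across two fields per sample (even split)
  twofield <- data.frame(
    fieldId = c(rbind(sprintf("s%d_f1", 1:3), sprintf("s%d_f2", 1:3))),
    positive = rep(c(TRUE, FALSE), 3))
  man2 <- rbind(man1,
                data.frame(group = "g", sampleId = sprintf("s%d", 1:3),
                           fieldId = sprintf("s%d_f2", 1:3)))
  expect_equal(fractionPositive(onefield, man1)$value,
               fractionPositive(twofield, man2)$value)
})

test_that("compareGroups dispatches on group count", {
  ss2 <- data.frame(group = rep(c("a", "b"), each = 3),
                    sampleId = 1:6, value = c(1, 2, 3, 4, 5, 6))
  expect_equal(compareGroups(ss2)@test, "MWU")
  ss3 <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                    sampleId = 1:9, value = rnorm(9))
  expect_equal(compareGroups(ss3)@test, "KW_Dunn")
})
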