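test_that("entropy matches the closed form", {
  expect_equal(shannonEntropy(c(0, 1, 0, 1)), 1)
  expect_equal(shannonEntropy(rep(1, 9)), 0)
  expect_equal(shannonEntropy(0.25, prob = TRUE), 0.8112781,
               tolerance = 1e-6)
  expect_equal(shannonEntropy(c(1, 0, 0, 0)),
               oracleEntropy(c(1, 0, 0, 0)))
  # concave-symmetric: H(p) = H(1 - p)
  for (p in c(0.1, 0.3, 0.45))
    expect_equal(shannonEntropy(p, prob = TRUE),
                 shannonEntropy(1 - p, prob = TRUE))
})

test_that("mutual information is symmetric, bounded and matches plug-in", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(mutualInformation(y, y), 1)
  expect_equal(mutualInformation(rep(1, 8), y), 0)
  # 2x2 counts (3,1;1,3) over n = 8: hand evaluation of the plug-in
  # formula gives H(.5) + H(.5) - H(3/8,1/8,1/8,3/8)
  col <- c(1, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(mutualInformation(col, y), 0.1887219, tolerance = 1e-6)
  set.seed(9)
  for (i in 1:10) {
    a <- rbinom(30, 1, 0.4); b <- rbinom(30, 1, 0.6)
    expect_equal(mutualInformation(a, b), mutualInformation(b, a))
    expect_equal(mutualInformation(a, b), oracleMI(a, b),
                 tolerance = 1e-12)
    expect_gte(mutualInformation(a, b), -1e-12)
    expect_lte(mutualInformation(a, b),
               min(shannonEntropy(a), shannonEntropy(b)) + 1e-12)
  }
  expect_error(mutualInformation(c(0, 1), c(0, 1, 1)), "length")
})

test_that("chi-squared p-values use the Pearson statistic at df 1", {
  # perfect independence: statistic 0, p = 1
  col <- rep(c(0, 1), each = 10)
  y <- rep(c(0, 1, 0, 1), each = 5)
  expect_equal(chiSquaredPValue(col, y), 1)
  # degenerate margin convention
  expect_equal(chiSquaredPValue(rep(1, 10), rbinom(10, 1, 0.5)), 1)
  # perfect dependence: statistic 20 at df 1
  expect_equal(chiSquaredPValue(col, col),
               stats::pchisq(20, 1, lower.tail = FALSE))
  set.seed(4)
  for (i in 1:10) {
    a <- rbinom(40, 1, 0.5); b <- rbinom(40, 1, 0.3)
    expect_equal(chiSquaredPValue(a, b), oracleChi2(a, b),
                 tolerance = 1e-12)
  }
})

test_that("frequency statistics follow the strict-threshold conventions", {
  vocab <- new("SubstructureVocabulary",
               counts = c(a = 1, b = 1, c = 2), nCompounds = 4L,
               config = enumConfig(0))
  fs <- frequencyStats(vocab)
  expect_equal(fs$pctSupport1, 200 / 3, tolerance = 1e-10)
  # strict < n/2 = 2 excludes c
  expect_equal(fs$pctSupportLtHalf, 200 / 3, tolerance = 1e-10)
  # count 2 = n/2 exactly: excluded by both strict inequalities
  expect_equal(fs$nGtHalf, 0L)
  fs3 <- frequencyStats(new("SubstructureVocabulary",
                            counts = c(a = 1, d = 3), nCompounds = 4L,
                            config = enumConfig(0)))
  expect_equal(fs3$nGtHalf, 1L)
  expect_equal(fs3$nGe90pct, 0L)

  allOnes <- new("SubstructureVocabulary",
                 counts = c(x = 1, y = 1), nCompounds = 3L,
                 config = enumConfig(0))
  expect_equal(frequencyStats(allOnes)$pctSupport1, 100)
})

test_that("frequency summaries are internally consistent on real vocabularies", {
  vocab <- buildVocabulary(cachedSets(60, 11))
  fs <- frequencyStats(vocab)
  expect_true(fs$pctSupport1 <= fs$pctSupportLe10)
  expect_true(fs$pctSupportLe10 <= fs$pctSupportLe100)
  expect_lte(fs$nGe90pct, fs$nGtHalf)
  expect_equal(fs$mT, vocabularySize(vocab))
})

test_that("frequency ranking equals entropy ranking when supports stay below n/2", {
  for (seed in c(5, 21)) {
    vocab <- buildVocabulary(cachedSets(40, seed, D = 2))
    n <- vocab@nCompounds
    cnt <- vocabularyCounts(vocab)
    sub <- cnt[cnt <= n / 2]
    ids <- as.numeric(names(sub))
    byFreq <- order(-as.numeric(sub), -ids)
    ent <- vapply(as.numeric(sub) / n, shannonEntropy, 0, prob = TRUE)
    byEntropy <- order(-ent, -ids)
    expect_equal(byFreq, byEntropy)
  }
})
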