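test_that("hash-based folding follows the identifier-mod-L contract", {
  expect_equal(hashFold(numeric(0), 8), rep(0L, 8))
  fp <- hashFold(c(5, 1029), 1024)
  expect_equal(which(fp == 1L), 6L)          # 1029 mod 1024 = 5 collides
  expect_equal(hashFold(0:15, 16), rep(1L, 16))
  # popcount <= set size, equality iff residues are collision-free
  set.seed(3)
  for (i in 1:20) {
    s <- sample(0:9999, sample(1:40, 1))
    L <- sample(c(8, 16, 64), 1)
    fp <- hashFold(s, L)
    expect_lte(sum(fp), length(s))
    expect_equal(sum(fp), length(unique(s %% L)))
    expect_equal(which(fp == 1L) - 1L, sort(unique(s %% L)))
  }
})

test_that("Sort & Slice ranks by support with the identifier tie-break", {
  # counts a(id 10): 3, b(id 1): 1, c(id 2): 1; at equal counts the
  # larger identifier takes the earlier rank, so L = 2 keeps [a, c]
  ss <- toySets(list(c(10, 1), c(10), c(10, 2)))
  cal <- calibratePooler(ss, "sort_slice", L = 2)
  expect_equal(poolIdentifiers(cal), c(10, 2))
  expect_equal(poolMethod(cal), "sort_slice")
  # L >= m_T keeps everything, rank 1 most frequent
  cal3 <- calibratePooler(ss, "sort_slice", L = 10)
  expect_equal(poolIdentifiers(cal3), c(10, 2, 1))
  expect_equal(cal3@counts, c(3, 1, 1))
})

test_that("selection transforms are one-hot and ignore unseen identifiers", {
  cal <- new("PoolerCalibration", method = "sort_slice", L = 2L,
             identifiers = c(7, 9), counts = c(2, 1), seed = 0L,
             meta = list())
  expect_equal(poolFingerprints(cal, c(7, 123)), c(1L, 0L))
  expect_equal(poolFingerprints(cal, numeric(0)), c(0L, 0L))
  # zero padding beyond the identifier list
  cal4 <- new("PoolerCalibration", method = "sort_slice", L = 4L,
              identifiers = c(7), counts = c(2), seed = 0L, meta = list())
  expect_equal(poolFingerprints(cal4, c(7, 9)), c(1L, 0L, 0L, 0L))
})

test_that("all four poolers emit binary length-L matrices", {
  ss <- cachedSets(60, 11)
  y <- compoundLabels(plantLabels(cachedLibrary(60, 11), c(`C(SC)` = 1),
                                  task = "classification"))
  for (method in c("folded", "sort_slice", "filtered", "mim")) {
    cal <- calibratePooler(ss, method, L = 48, labels = y, seed = 2)
    fp <- poolFingerprints(cal, ss)
    expect_equal(dim(fp), c(60L, 48L))
    expect_true(all(fp %in% c(0L, 1L)))
    if (method != "folded") {
      expect_equal(anyDuplicated(poolIdentifiers(cal)), 0L)
      expect_lte(length(poolIdentifiers(cal)), 48L)
    }
  }
})

test_that("Sort & Slice counts are monotone and popcounts match at L >= m_T", {
  ss <- cachedSets(60, 11)
  vocab <- buildVocabulary(ss)
  cal <- calibratePooler(vocab, "sort_slice", L = 128)
  expect_true(all(diff(cal@counts) <= 0))
  # limit case: no slicing, fingerprint popcount equals the set size
  mT <- vocabularySize(vocab)
  calAll <- calibratePooler(vocab, "sort_slice", L = mT + 50)
  fp <- poolFingerprints(calAll, ss)
  expect_equal(unname(rowSums(fp)), unname(lengths(identifierSets(ss))))
  expect_equal(ncol(fp), mT + 50)
})

test_that("filtering removes singleton supports first", {
  # ids 10/20 supported twice, id 5 once; L = m_T - 1 must drop id 5
  ss <- toySets(list(c(10, 20, 5), c(10, 20)))
  y <- c(0, 1)
  cal <- calibratePooler(ss, "filtered", L = 2, labels = y, seed = 1)
  expect_setequal(poolIdentifiers(cal), c(10, 20))
})

test_that("filtering removes non-closed environments (nested radii)", {
  # two identical compounds: every identifier has support {1,2}; the
  # closed identifiers are exactly the three radius-0 environments
  ss <- enumerateSubstructures(c("CCF", "CCF"), enumConfig(4))
  r0 <- unique(ss@traces[[1]]$id[ss@traces[[1]]$radius == 0])
  cal <- calibratePooler(ss, "filtered", L = 3, labels = c(0, 1), seed = 9)
  expect_setequal(poolIdentifiers(cal), r0)
})

test_that("filtering step 3 keeps the strongest chi-squared dependence", {
  # feature A tracks the label exactly; B is weaker; C is a singleton
  y <- c(1, 1, 1, 0, 0, 0)
  sets <- list(c(100, 200), c(100), c(100), c(200), c(300), numeric(0))
  ss <- toySets(sets)
  cal <- calibratePooler(ss, "filtered", L = 1, labels = y, seed = 4)
  expect_equal(poolIdentifiers(cal), 100)
  # oracle: enumerate all chi-squared p-values by hand
  pA <- oracleChi2(presenceColumn(ss, 100), y)
  pB <- oracleChi2(presenceColumn(ss, 200), y)
  expect_lt(pA, pB)
})

test_that("MIM collapses identical supports and maximises information", {
  # extremes: a feature identical to the balanced label (1 bit) beats a
  # constant feature (0 bits)
  y <- rep(c(1, 0), each = 4)
  sets <- lapply(seq_along(y), function(i)
    c(if (y[i] == 1) 100 else numeric(0), 500))
  cal <- calibratePooler(toySets(sets), "mim", L = 1, labels = y, seed = 1)
  expect_equal(poolIdentifiers(cal), 100)
  expect_equal(cal@meta$mi, 1)

  # duplicate-support pair: exactly one member survives step 1
  sets2 <- list(c(10, 11, 30), c(10, 11), c(30))
  cal2 <- calibratePooler(toySets(sets2), "mim", L = 2,
                          labels = c(1, 0, 1), seed = 5)
  expect_length(intersect(poolIdentifiers(cal2), c(10, 11)), 1L)

  # 8-compound fixture, three features with distinct plug-in MI
  y3 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  sets3 <- lapply(1:8, function(i) c(
    if (i <= 4) 1000 else numeric(0),          # MI = 1 bit
    if (i %in% c(1, 2, 3, 5)) 2000 else numeric(0),  # moderate MI
    if (i %in% c(1, 5)) 3000 else numeric(0)))       # zero MI
  ssm <- toySets(sets3)
  miVals <- vapply(c(1000, 2000, 3000), function(id)
    oracleMI(presenceColumn(ssm, id), y3), 0)
  expect_equal(order(miVals, decreasing = TRUE), 1:3)
  cal3 <- calibratePooler(ssm, "mim", L = 2, labels = y3, seed = 2)
  expect_setequal(poolIdentifiers(cal3), c(1000, 2000))
  expect_equal(sort(cal3@meta$mi, decreasing = TRUE),
               sort(miVals[1:2], decreasing = TRUE))
})

test_that("supervised calibrations are reproducible under a seed", {
  ss <- cachedSets(60, 11)
  y <- binarizeLabels(compoundLabels(plantLabels(
    cachedLibrary(60, 11), c(CCO = 1, `C(SC)` = 2), noiseSd = 0.2,
    task = "regression", seed = 3)))
  for (method in c("filtered", "mim")) {
    a <- calibratePooler(ss, method, L = 32, labels = y, seed = 7)
    b <- calibratePooler(ss, method, L = 32, labels = y, seed = 7)
    expect_identical(poolIdentifiers(a), poolIdentifiers(b))
  }
})

test_that("degenerate labels error for filtering and warn for MIM", {
  ss <- toySets(list(c(1, 2), c(1), c(2)))
  expect_error(calibratePooler(ss, "filtered", L = 1,
                               labels = c(1, 1, 1), seed = 0),
               "degenerate")
  expect_warning(calibratePooler(ss, "mim", L = 1,
                                 labels = c(1, 1, 1), seed = 0),
                 "degenerate")
})

test_that("median binarisation maps ties down and splits above/below", {
  expect_equal(binarizeLabels(c(0, 1, 1, 0)), c(0L, 1L, 1L, 0L))
  expect_equal(binarizeLabels(c(1.2, 3.4, 2.0, 0.1)), c(0L, 1L, 1L, 0L))
  expect_equal(binarizeLabels(c(5, 5, 7)), c(0L, 0L, 1L))
})

test_that("calibrations round-trip through JSON", {
  ss <- toySets(list(c(10, 1), c(10), c(10, 2)))
  cal <- calibratePooler(ss, "sort_slice", L = 2)
  path <- withr::local_tempfile(fileext = ".json")
  writeCalibration(cal, path)
  back <- readCalibration(path)
  expect_equal(poolIdentifiers(back), poolIdentifiers(cal))
  expect_equal(back@method, cal@method)
  expect_equal(back@L, cal@L)
})
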