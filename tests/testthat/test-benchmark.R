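test_that("Bemis-Murcko scaffolds strip side chains and handle acyclic input", {
  sc <- murckoScaffold(c("CCO", "Cc1ccccc1", "CCc1ccccc1CC(C)C"))
  expect_equal(sc[1], "")
  expect_equal(sc[2], "c1ccccc1")
  expect_equal(sc[3], "c1ccccc1")
  # two linked rings keep their linker
  sc2 <- murckoScaffold("CC1CCC1CCc1ccccc1C")
  expect_match(sc2, "1")
  expect_equal(murckoScaffold("c1ccccc1"), "c1ccccc1")
})

test_that("split plans partition the data and are seed-deterministic", {
  lib <- cachedLibrary(60, 11)
  for (scheme in c("random", "scaffold")) {
    plan <- makeSplits(lib, scheme, nFolds = 2, seeds = 1:3)
    for (a in plan@assignments) {
      expect_length(a, 60L)
      expect_setequal(unique(a), 1:2)
    }
  }
  # random folds are balanced exactly (scaffold folds balance only up
  # to the largest scaffold group)
  a <- makeSplits(lib, "random", nFolds = 2, seeds = 9)@assignments[[1]]
  expect_equal(sum(a == 1), 30)
  p1 <- makeSplits(lib, "random", seeds = 5)@assignments[[1]]
  p2 <- makeSplits(lib, "random", seeds = 5)@assignments[[1]]
  expect_identical(p1, p2)
})

test_that("scaffold folds never share a scaffold", {
  lib <- cachedLibrary(60, 11)
  scaffolds <- murckoScaffold(compoundSmiles(lib))
  plan <- makeSplits(lib, "scaffold", nFolds = 2, seeds = 1:3)
  for (a in plan@assignments)
    for (sc in unique(scaffolds))
      expect_length(unique(a[scaffolds == sc]), 1L)
})

test_that("stratified splits balance the positive class exactly", {
  y <- c(rep(1, 8), rep(0, 792))
  cs <- compoundSet(seq_along(y), rep("C", length(y)), y,
                    taskType = "classification")
  plan <- makeSplits(cs, "stratified", nFolds = 2, seeds = 1:2)
  for (a in plan@assignments) {
    expect_equal(sum(y == 1 & a == 1), 4)
    expect_equal(sum(y == 1 & a == 2), 4)
  }
})

test_that("metrics match their oracles", {
  expect_equal(computeMetric(c(1, 2, 3), c(1, 2, 3), "mae"), 0)
  expect_equal(computeMetric(c(.9, .8, .4, .2), c(1, 0, 1, 0), "auroc"),
               0.75)
  expect_equal(computeMetric(c(.9, .8, .2), c(1, 1, 0), "auroc"), 1)
  set.seed(12)
  for (i in 1:8) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(30)
    expect_equal(computeMetric(s, y, "auroc"), oracleAUROC(s, y))
    expect_equal(computeMetric(s, y, "auprc"), oracleAUPRC(s, y))
    p <- rnorm(30); t <- rnorm(30)
    expect_equal(computeMetric(p, t, "mae"), mean(abs(p - t)))
  }
  expect_error(computeMetric(c(.1, .2), c(1, 1), "auroc"), "single")
  expect_error(computeMetric(1:3, 1:2, "mae"), "length")
})

test_that("rank-statistic AUROC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rbinom(50, 1, 0.5)
  s <- rnorm(50) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(computeMetric(s, y, "auroc"), ref, tolerance = 1e-12)
})

test_that("benchmark bookkeeping: runs, rows and determinism", {
  lib <- plantLabels(cachedLibrary(40, 7), c(CCO = 1, `C(SC)` = 2),
                     noiseSd = 0.3, task = "regression", seed = 2)
  res <- runBenchmark(lib, methods = c("folded", "sort_slice"),
                      lengths = 32L, diameters = 2L, seeds = 1L,
                      numTrees = 50L)
  expect_equal(nrow(res), 4L)                 # 2 methods x 2 folds
  summ <- summarizeBenchmark(res)
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$nRuns, c(2, 2))
  # mean/sd recompute from the per-run values
  for (m in summ$method) {
    v <- res$value[res$method == m]
    expect_equal(summ$mean[summ$method == m], mean(v))
    expect_equal(summ$sd[summ$method == m], stats::sd(v))
  }
  res2 <- runBenchmark(lib, methods = c("folded", "sort_slice"),
                       lengths = 32L, diameters = 2L, seeds = 1L,
                       numTrees = 50L)
  expect_equal(res$value, res2$value)
})

test_that("calibration sees only the training fold (no test leakage)", {
  lib <- cachedLibrary(40, 7)
  sets <- cachedSets(40, 7)
  trainIdx <- 1:20
  calFull <- calibratePooler(sets[trainIdx], "sort_slice", L = 64)
  # enumerating the training compounds alone gives the same calibration
  setsTrain <- enumerateSubstructures(lib[trainIdx], enumConfig(4))
  calAlone <- calibratePooler(setsTrain, "sort_slice", L = 64)
  expect_identical(poolIdentifiers(calFull), poolIdentifiers(calAlone))
  expect_identical(calFull@counts, calAlone@counts)
})

test_that("the MLP family is documented but unavailable", {
  expect_error(fitPredict(matrix(0, 2, 2), 1:2, matrix(0, 2, 2),
                          family = "mlp"), "deep-learning")
})
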