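test_that("standardisation keeps clean molecules, desalts and neutralises", {
  res <- standardizeSmiles(c("CCO", "CC(=O)[O-].[Na+]", "C1CC1("))
  expect_equal(res$ok, c(TRUE, TRUE, FALSE))
  expect_equal(res$smiles[1], "CCO")
  # sodium acetate: counterion dropped, carboxylate protonated
  expect_equal(res$smiles[2], "CC(=O)O")
  expect_match(res$reason[3], "syntax")
})

test_that("standardisation strips isotopes but preserves stereo", {
  res <- standardizeSmiles(c("[13CH3]Cl", "C[C@H](N)C(=O)O"))
  expect_true(all(res$ok))
  expect_equal(res$smiles[1], "CCl")
  expect_match(res$smiles[2], "@", fixed = TRUE)
})

test_that("zwitterions neutralise; charge-separated groups survive", {
  res <- standardizeSmiles(c("[NH3+]CC(=O)[O-]",      # glycine zwitterion
                             "C[N+](C)(C)C",          # quaternary ammonium
                             "CC[N+](=O)[O-]"))       # nitroethane
  expect_true(all(res$ok))
  expect_false(grepl("[+-]", res$smiles[1]))
  expect_match(res$smiles[2], "N+", fixed = TRUE)
  expect_match(res$smiles[3], "-", fixed = TRUE)
})

test_that("cleaning collapses duplicates and drops mixtures", {
  cs <- compoundSet(letters[1:3], c("CCO", "OCC", "CCN"))
  cl <- cleanCompounds(cs, seed = 1)
  expect_equal(length(cl), 2L)
  expect_setequal(compoundSmiles(cl), c("CCO", "CCN"))

  cs2 <- compoundSet(c("x", "y", "z"), c("CCO.CC", "CCC", "CCCC"))
  cl2 <- cleanCompounds(cs2, seed = 0)
  expect_equal(length(cl2), 2L)
  log <- attr(cl2, "dropLog")
  expect_match(log$reason[log$id == "x"], "fragments")

  cs3 <- compoundSet(1:3, c("CC", "CCC", "CCCC"))
  expect_equal(length(cleanCompounds(cs3, seed = 5)), 3L)
})

test_that("cleaning is idempotent and seed changes only duplicate identity", {
  cs <- compoundSet(1:6, c("CCO", "OCC", "C(C)O", "CCN", "c1ccccc1",
                           "C1=CC=CC=C1"))
  sizes <- vapply(1:5, function(s) length(cleanCompounds(cs, seed = s)), 0L)
  expect_true(all(sizes == 3L))
  ids1 <- compoundIds(cleanCompounds(cs, seed = 1))
  ids4 <- compoundIds(cleanCompounds(cs, seed = 4))
  expect_equal(length(ids1), length(ids4))

  cl <- cleanCompounds(cs, seed = 1)
  cl2 <- cleanCompounds(cl, seed = 99)
  expect_equal(compoundSmiles(cl2), compoundSmiles(cl))
  expect_equal(compoundIds(cl2), compoundIds(cl))
})

test_that("every surviving SMILES parses as one connected component", {
  lib <- cachedLibrary(60, 11)
  cl <- cleanCompounds(lib, seed = 2)
  expect_false(any(grepl(".", compoundSmiles(cl), fixed = TRUE)))
  ss <- enumerateSubstructures(cl, enumConfig(0))
  expect_true(all(lengths(identifierSets(ss)) > 0))
})

test_that("all records rejected raises an empty-dataset error", {
  cs <- compoundSet(1:2, c("C1CC1(", "notasmiles(("))
  expect_error(cleanCompounds(cs, seed = 0), "empty")
})

test_that("compound tables round-trip through CSV", {
  cs <- compoundSet(c("a", "b"), c("CCO", "CCN"), c(1.5, -0.3),
                    taskType = "regression")
  path <- withr::local_tempfile(fileext = ".csv")
  writeCompoundTable(cs, path)
  back <- readCompoundTable(path, smilesCol = "smiles",
                            labelCol = "label", idCol = "id",
                            taskType = "regression")
  expect_equal(compoundSmiles(back), compoundSmiles(cs))
  expect_equal(compoundLabels(back), compoundLabels(cs))
})

test_that("fingerprint matrices round-trip in dense and sparse text", {
  m <- matrix(c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE)
  rownames(m) <- c("c1", "c2")
  dense <- withr::local_tempfile(fileext = ".tsv")
  writeFingerprints(m, dense, "dense")
  expect_length(readLines(dense), 3L)        # header + 2 data lines
  back <- readFingerprints(dense, "dense")
  expect_equal(unname(back), unname(m))
  expect_equal(rownames(back), rownames(m))

  sparse <- withr::local_tempfile(fileext = ".txt")
  writeFingerprints(m, sparse, "sparse")
  expect_length(readLines(sparse), 3L)       # "n L" header + 2 triples
  expect_equal(readFingerprints(sparse, "sparse"), unname(m))

  set.seed(42)
  for (i in 1:3) {
    r <- matrix(rbinom(60, 1, 0.3), nrow = 5)
    p <- withr::local_tempfile()
    writeFingerprints(r, p, "sparse")
    expect_equal(readFingerprints(p, "sparse"), r)
    writeFingerprints(r, p, "dense")
    expect_equal(unname(readFingerprints(p, "dense")), r)
  }
  expect_error(writeFingerprints(matrix(c(0, 2), 1), tempfile()),
               "binary")
  expect_error(writeFingerprints(list(1, c(1, 2)), tempfile()),
               "matrix")
})
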