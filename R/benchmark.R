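# Scaled-down benchmarking harness: splits, repeated cross-validation,
# random-forest models, and metrics over the pooling-method grid.

#' Bemis-Murcko scaffold of a molecule
#'
#' The molecular framework left after iteratively pruning terminal
#' (degree-1) heavy atoms: ring systems plus the linkers connecting
#' them, returned as a canonical SMILES string. Acyclic molecules have
#' no scaffold and return the empty string.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of scaffold SMILES ("" for acyclic
#'   molecules).
#' @export
murckoScaffold <- function(smiles) {
  graphs <- .molFromSmilesBatch(.canonicalSmilesBatch(smiles))
  vapply(graphs, function(g) {
    if (is.null(g) || g$natoms == 0L) return(NA_character_)
    keep <- rep(TRUE, g$natoms)
    deg <- lengths(g$adj)
    repeat {
      leaves <- which(keep & deg <= 1L)
      if (!length(leaves)) break
      keep[leaves] <- FALSE
      for (a in leaves)
        for (nb in g$adj[[a]]) if (keep[nb]) deg[nb] <- deg[nb] - 1L
      deg[leaves] <- 0L
    }
    if (!any(keep)) return("")
    sc <- .subgraphCanonical(g, which(keep))
    if (is.na(sc)) "" else sc
  }, "")
}

#' Build a cross-validation split plan
#'
#' \code{random}: seeded shuffle split into equal folds.
#' \code{stratified}: per-class seeded shuffle split, keeping each
#' fold's class balance within one compound of the global rate
#' (classification tasks only).
#' \code{scaffold}: compounds are grouped by Bemis-Murcko scaffold
#' (acyclic molecules form one group with scaffold \code{""}), groups
#' are ordered by descending size with seeded shuffling among equal
#' sizes, and each group is assigned greedily to the currently smallest
#' fold, so no scaffold spans two folds.
#'
#' @param x a \code{CompoundSet}.
#' @param scheme \code{"random"}, \code{"stratified"} or
#'   \code{"scaffold"}.
#' @param nFolds number of folds (default 2).
#' @param seeds integer vector of repetition seeds (default
#'   \code{1:3}).
#' @return A \code{\link{SplitPlan-class}}.
#' @export
makeSplits <- function(x, scheme = c("random", "stratified", "scaffold"),
                       nFolds = 2L, seeds = 1:3) {
  scheme <- match.arg(scheme)
  stopifnot(is(x, "CompoundSet"))
  n <- length(x)
  nFolds <- as.integer(nFolds)
  scaffolds <- NULL
  if (scheme == "scaffold") {
    scaffolds <- murckoScaffold(compoundSmiles(x))
    scaffolds[is.na(scaffolds)] <- ""
  }
  if (scheme == "stratified") {
    y <- compoundLabels(x)
    if (anyNA(y) || !all(y %in% c(0, 1)))
      stop("stratified splitting needs binary labels")
  }
  assignments <- lapply(seeds, function(seed) .withSeed(seed, {
    fold <- integer(n)
    if (scheme == "random") {
      fold[sample.int(n)] <- rep(seq_len(nFolds), length.out = n)
    } else if (scheme == "stratified") {
      y <- compoundLabels(x)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx[sample.int(length(idx))]] <-
          rep(seq_len(nFolds), length.out = length(idx))
      }
    } else {
      groups <- split(seq_len(n), scaffolds)
      sizes <- lengths(groups)
      ord <- order(-sizes, sample.int(length(groups)))
      foldSize <- numeric(nFolds)
      for (g in ord) {
        target <- which.min(foldSize)
        fold[groups[[g]]] <- target
        foldSize[target] <- foldSize[target] + sizes[g]
      }
    }
    fold
  }))
  new("SplitPlan", scheme = scheme, nFolds = nFolds,
      seeds = as.integer(seeds), assignments = assignments)
}

#' Prediction metrics
#'
#' \code{mae}: mean absolute error. \code{auroc}: area under the ROC
#' curve via the pairwise rank statistic (ties count 1/2).
#' \code{auprc}: area under the precision-recall curve by step
#' integration over recall increments (average precision).
#'
#' @param predictions numeric predictions (scores for classification).
#' @param truth numeric ground truth (binary for auroc/auprc).
#' @param metric \code{"mae"}, \code{"auroc"} or \code{"auprc"}.
#' @return a single numeric value.
#' @examples
#' computeMetric(c(.9, .8, .4, .2), c(1, 0, 1, 0), "auroc")  # 0.75
#' @export
computeMetric <- function(predictions, truth,
                          metric = c("mae", "auroc", "auprc")) {
  metric <- match.arg(metric)
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  if (metric == "mae") return(mean(abs(predictions - truth)))
  if (!all(truth %in% c(0, 1)))
    stop(metric, " needs binary truth labels")
  nPos <- sum(truth == 1); nNeg <- sum(truth == 0)
  if (nPos == 0 || nNeg == 0)
    stop(metric, " undefined: truth contains a single class")
  if (metric == "auroc") {
    r <- rank(predictions, ties.method = "average")
    return((sum(r[truth == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg))
  }
  # auprc: walk the ranking from the highest score; precision summed at
  # each recall step (ties processed in one block, trapezoid within)
  ord <- order(-predictions, truth)
  y <- truth[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  prec <- tp / (tp + fp)
  rec <- tp / nPos
  prevRec <- c(0, rec[-length(rec)])
  sum(prec * (rec - prevRec))
}

#' Fit a model and predict
#'
#' Random forests are fitted with \pkg{ranger} library defaults, except
#' that regression forests subsample \code{floor(sqrt(p))} features per
#' split (the square-root rule) to add randomness. The multilayer
#' perceptron configuration documented for this harness (5 hidden
#' layers of 512 rectified units, batch normalisation, dropout 0.25,
#' batch size 64, 250 epochs, AdamW with decoupled weight decay 0.1,
#' initial learning rate 1e-3 decayed by 0.98/epoch with floor 1e-5)
#' requires a deep-learning backend and is not available in this
#' package; requesting it raises an error.
#'
#' @param xTrain,yTrain training fingerprints and labels.
#' @param xTest test fingerprints.
#' @param task \code{"regression"} or \code{"classification"}.
#' @param family \code{"rf"} (random forest) or \code{"mlp"}.
#' @param seed integer seed for the forest.
#' @param numTrees number of trees (library default 500).
#' @return numeric predictions (class-1 probabilities for
#'   classification).
#' @export
fitPredict <- function(xTrain, yTrain, xTest,
                       task = c("regression", "classification"),
                       family = c("rf", "mlp"), seed = 0L,
                       numTrees = 500L) {
  task <- match.arg(task)
  family <- match.arg(family)
  if (family == "mlp")
    stop("the multilayer-perceptron model requires a deep-learning ",
         "backend; use family = 'rf'")
  colnames(xTrain) <- colnames(xTest) <- sprintf("b%d", seq_len(ncol(xTrain)))
  if (task == "regression") {
    fit <- ranger::ranger(y = yTrain, x = as.data.frame(xTrain),
                          num.trees = numTrees,
                          mtry = max(1L, floor(sqrt(ncol(xTrain)))),
                          seed = seed, num.threads = 1L)
    stats::predict(fit, as.data.frame(xTest), num.threads = 1L)$predictions
  } else {
    fit <- ranger::ranger(y = factor(yTrain, levels = c(0, 1)),
                          x = as.data.frame(xTrain),
                          num.trees = numTrees, probability = TRUE,
                          seed = seed, num.threads = 1L)
    stats::predict(fit, as.data.frame(xTest),
                   num.threads = 1L)$predictions[, "1"]
  }
}

#' Run the pooling-method benchmark grid
#'
#' Repeated k-fold cross-validation of pooling methods over an
#' enumeration/length grid. For every (seed, fold) the pooling operator
#' is calibrated on the training fold only (the test fold never touches
#' the calibration), fingerprints are computed for both folds, a model
#' is fitted and the test-fold metric recorded.
#'
#' @param x a labelled \code{CompoundSet} (cleaned).
#' @param methods character vector of pooling methods.
#' @param lengths integer vector of fingerprint lengths L.
#' @param diameters even integers D.
#' @param invariants \code{"standard"} and/or \code{"pharmacophoric"}.
#' @param useChirality chirality flag for enumeration.
#' @param scheme split scheme, see \code{\link{makeSplits}}.
#' @param seeds repetition seeds.
#' @param nFolds folds per repetition.
#' @param metric metric name; default chosen from the task type (MAE
#'   for regression, AUROC for classification).
#' @param family model family (\code{"rf"}).
#' @param numTrees trees per forest.
#' @return data.frame with one row per (grid cell, seed, fold):
#'   columns dataset, scheme, model, method, D, invariants, L, seed,
#'   fold, metric, value.
#' @export
runBenchmark <- function(x, methods = c("folded", "sort_slice"),
                         lengths = 1024L, diameters = 4L,
                         invariants = "standard", useChirality = TRUE,
                         scheme = "random", seeds = 1:3, nFolds = 2L,
                         metric = NULL, family = "rf",
                         numTrees = 500L) {
  stopifnot(is(x, "CompoundSet"))
  task <- taskType(x)
  if (task == "unlabelled") stop("benchmarking needs a labelled dataset")
  if (is.null(metric))
    metric <- if (task == "regression") "mae" else "auroc"
  y <- compoundLabels(x)
  splits <- makeSplits(x, scheme = scheme, nFolds = nFolds, seeds = seeds)
  rows <- list()
  for (inv in invariants) for (D in diameters) {
    sets <- enumerateSubstructures(
      x, enumConfig(maxDiameter = D, invariants = inv,
                    useChirality = useChirality))
    for (si in seq_along(seeds)) {
      fold <- splits@assignments[[si]]
      for (f in seq_len(nFolds)) {
        trainIdx <- which(fold != f)
        testIdx <- which(fold == f)
        trainSets <- sets[trainIdx]
        for (method in methods) for (L in lengths) {
          cal <- calibratePooler(trainSets, method = method, L = L,
                                 labels = y[trainIdx],
                                 seed = seeds[si])
          fpTrain <- poolFingerprints(cal, trainSets)
          fpTest <- poolFingerprints(cal, sets[testIdx])
          pred <- fitPredict(fpTrain, y[trainIdx], fpTest,
                             task = task, family = family,
                             seed = seeds[si], numTrees = numTrees)
          val <- computeMetric(pred, y[testIdx], metric)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = x@provenance, scheme = scheme, model = family,
            method = method, D = D, invariants = inv, L = L,
            seed = seeds[si], fold = f, metric = metric, value = val,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarise benchmark runs
#'
#' Mean and standard deviation of the metric over the (seed, fold) runs
#' of every grid cell.
#'
#' @param results data.frame from \code{\link{runBenchmark}}.
#' @return aggregated data.frame with columns \code{mean}, \code{sd}
#'   and \code{nRuns} per grid cell.
#' @export
summarizeBenchmark <- function(results) {
  keys <- c("dataset", "scheme", "model", "method", "D", "invariants",
            "L", "metric")
  agg <- stats::aggregate(results$value, results[keys],
                   function(v) c(mean = mean(v), sd = stats::sd(v),
                                 n = length(v)))
  out <- cbind(agg[keys], as.data.frame(agg$x))
  names(out)[names(out) == "n"] <- "nRuns"
  out
}
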