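# Shared fixtures and independent oracles.

# Toy SubstructureSets built directly from identifier lists (no
# molecular graphs; only usable where the environment-isomorphism step
# cannot trigger, i.e. when no two listed identifiers share a support).
toySets <- function(sets, ids = as.character(seq_along(sets))) {
  n <- length(sets)
  new("SubstructureSets", ids = ids,
      sets = lapply(sets, function(s) sort(unique(as.numeric(s)))),
      traces = rep(list(data.frame(id = numeric(0), atom = integer(0),
                                   radius = integer(0))), n),
      graphs = vector("list", n),
      config = enumConfig(0))
}

# Memoised synthetic libraries + enumerations (enumeration is the
# expensive step; several files reuse the same fixtures).
.fixtureCache <- new.env(parent = emptyenv())

cachedLibrary <- function(n, seed, ...) {
  key <- paste0("lib_", n, "_", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateLibrary(
      fixtureSpec(nCompounds = n, seed = seed, ...))
  .fixtureCache[[key]]
}

cachedSets <- function(n, seed, D = 4) {
  key <- paste0("sets_", n, "_", seed, "_", D)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- enumerateSubstructures(
      cachedLibrary(n, seed), enumConfig(D))
  .fixtureCache[[key]]
}

# --- independent oracles ----------------------------------------------------

# Plug-in entropy of an arbitrary discrete sample, from first
# principles.
oracleEntropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# Mutual information via three explicit entropy estimates.
oracleMI <- function(col, y)
  oracleEntropy(col) + oracleEntropy(y) -
    oracleEntropy(paste(col, y))

# Chi-squared p-value through R's own independence test (no continuity
# correction); degenerate margins give p = 1 by convention.
oracleChi2 <- function(col, y) {
  if (length(unique(col)) < 2 || length(unique(y)) < 2) return(1)
  suppressWarnings(
    stats::chisq.test(table(col, y), correct = FALSE)$p.value)
}

# AUROC by brute force over all (positive, negative) score pairs.
oracleAUROC <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# AUPRC as precision accumulated over recall steps, walking the ranked
# list one element at a time.
oracleAUPRC <- function(scores, y) {
  ord <- order(-scores, y)
  y <- y[ord]
  tp <- 0; fp <- 0; area <- 0; nPos <- sum(y)
  prevRec <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) tp <- tp + 1 else fp <- fp + 1
    rec <- tp / nPos
    area <- area + (rec - prevRec) * tp / (tp + fp)
    prevRec <- rec
  }
  area
}

# Presence column of one identifier across a SubstructureSets.
presenceColumn <- function(sets, id)
  vapply(identifierSets(sets), function(s) as.integer(id %in% s), 0L)
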