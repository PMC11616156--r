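#' @import methods
NULL

#' Enumeration configuration for circular substructures
#'
#' Fixes the three hyperparameters of circular-substructure enumeration:
#' the maximal substructure diameter \code{D} (an even non-negative
#' integer, so that substructures up to radius \code{D/2} are detected),
#' the list of atomic invariants used to seed the iterative environment
#' hashing (\code{"standard"} for ECFP-style invariants,
#' \code{"pharmacophoric"} for the six binary FCFP-style invariants), and
#' whether a tetrahedral R/S chirality tag is appended to the invariants.
#'
#' @slot maxDiameter even non-negative integer; substructures of diameter
#'   \code{0, 2, ..., maxDiameter} are enumerated.
#' @slot invariants \code{"standard"} or \code{"pharmacophoric"}.
#' @slot useChirality logical flag.
#' @export
setClass("EnumConfig",
  representation(
    maxDiameter = "integer",
    invariants = "character",
    useChirality = "logical"
  )
)

setValidity("EnumConfig", function(object) {
  msg <- character(0)
  d <- object@maxDiameter
  if (length(d) != 1L || is.na(d) || d < 0L || d %% 2L != 0L)
    msg <- c(msg, "maxDiameter must be a single even non-negative integer")
  if (length(object@invariants) != 1L ||
      !object@invariants %in% c("standard", "pharmacophoric"))
    msg <- c(msg, "invariants must be 'standard' or 'pharmacophoric'")
  if (length(object@useChirality) != 1L || is.na(object@useChirality))
    msg <- c(msg, "useChirality must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct an enumeration configuration
#'
#' @param maxDiameter even non-negative integer, default 4 (the common
#'   ECFP4 setting).
#' @param invariants \code{"standard"} (ECFP) or \code{"pharmacophoric"}
#'   (FCFP).
#' @param useChirality append a tetrahedral chirality tag to the atomic
#'   invariants (default \code{TRUE}).
#' @return An \code{EnumConfig} object.
#' @examples
#' enumConfig(maxDiameter = 2, invariants = "standard")
#' @export
enumConfig <- function(maxDiameter = 4L, invariants = c("standard", "pharmacophoric"),
                       useChirality = TRUE) {
  invariants <- match.arg(invariants)
  if (length(maxDiameter) != 1L || is.na(maxDiameter) ||
      maxDiameter != as.integer(maxDiameter))
    stop("maxDiameter must be a single integer")
  if (as.integer(maxDiameter) %% 2L != 0L)
    stop("maxDiameter must be even (it is a substructure *diameter*)")
  new("EnumConfig", maxDiameter = as.integer(maxDiameter),
      invariants = invariants, useChirality = isTRUE(useChirality))
}

setMethod("show", "EnumConfig", function(object) {
  cat(sprintf("EnumConfig: D=%d, invariants=%s, chirality=%s\n",
              object@maxDiameter, object@invariants,
              if (object@useChirality) "on" else "off"))
})

#' A table of compounds with optional labels
#'
#' The basic dataset container: parallel vectors of compound identifiers,
#' SMILES strings and numeric labels, plus a task type and a free-text
#' provenance tag. Produced by \code{\link{readCompoundTable}},
#' \code{\link{cleanCompounds}} and \code{\link{generateLibrary}}.
#'
#' @slot id character vector of unique record identifiers.
#' @slot smiles character vector of SMILES strings.
#' @slot label numeric vector (NA when unlabelled).
#' @slot taskType one of \code{"regression"}, \code{"classification"},
#'   \code{"unlabelled"}.
#' @slot provenance free-text source tag.
#' @slot extra data.frame of per-compound metadata (may have 0 columns).
#' @export
setClass("CompoundSet",
  representation(
    id = "character",
    smiles = "character",
    label = "numeric",
    taskType = "character",
    provenance = "character",
    extra = "data.frame"
  )
)

setValidity("CompoundSet", function(object) {
  msg <- character(0)
  n <- length(object@id)
  if (length(object@smiles) != n || length(object@label) != n)
    msg <- c(msg, "id, smiles and label must have equal length")
  if (anyDuplicated(object@id))
    msg <- c(msg, "record ids must be unique")
  if (!object@taskType %in% c("regression", "classification", "unlabelled"))
    msg <- c(msg, "taskType must be regression, classification or unlabelled")
  if (object@taskType == "classification") {
    lab <- object@label[!is.na(object@label)]
    if (length(lab) && !all(lab %in% c(0, 1)))
      msg <- c(msg, "classification labels must lie in {0, 1}")
  }
  if (nrow(object@extra) && nrow(object@extra) != n)
    msg <- c(msg, "extra metadata must have one row per compound")
  if (length(msg)) msg else TRUE
})

#' @describeIn CompoundSet-class constructor.
#' @param id,smiles,label,taskType,provenance,extra see slots.
#' @export
compoundSet <- function(id, smiles, label = rep(NA_real_, length(id)),
                        taskType = "unlabelled", provenance = "",
                        extra = data.frame()) {
  new("CompoundSet", id = as.character(id), smiles = as.character(smiles),
      label = as.numeric(label), taskType = taskType,
      provenance = provenance, extra = extra)
}

setMethod("show", "CompoundSet", function(object) {
  cat(sprintf("CompoundSet with %d compounds (%s%s)\n",
              length(object@id), object@taskType,
              if (nzchar(object@provenance))
                paste0(", ", object@provenance) else ""))
  k <- min(3L, length(object@id))
  if (k > 0)
    for (i in seq_len(k))
      cat(sprintf("  %s  %s  %s\n", object@id[i], object@smiles[i],
                  format(object@label[i])))
  if (length(object@id) > k) cat("  ...\n")
})

setMethod("length", "CompoundSet", function(x) length(x@id))

setMethod("[", "CompoundSet", function(x, i, j, ..., drop = TRUE) {
  idx <- seq_along(x@id)[i]
  new("CompoundSet", id = x@id[idx], smiles = x@smiles[idx],
      label = x@label[idx], taskType = x@taskType,
      provenance = x@provenance,
      extra = if (nrow(x@extra)) x@extra[idx, , drop = FALSE]
              else x@extra)
})

#' Per-compound sets of circular-substructure identifiers
#'
#' The result of substructure enumeration over a set of compounds. For
#' each compound it stores the set of unique 32-bit substructure
#' identifiers, an identifier trace (which centre atom and radius each
#' identifier came from, needed to reconstruct atom environments), and the
#' parsed molecular graph.
#'
#' @slot ids compound identifiers.
#' @slot sets list of numeric vectors; each is the compound's set of
#'   identifiers in \code{[0, 2^32)}.
#' @slot traces list of data.frames with columns \code{id}, \code{atom},
#'   \code{radius}.
#' @slot graphs list of internal molecular-graph objects.
#' @slot config the \code{EnumConfig} used.
#' @export
setClass("SubstructureSets",
  representation(
    ids = "character",
    sets = "list",
    traces = "list",
    graphs = "list",
    config = "EnumConfig"
  )
)

setValidity("SubstructureSets", function(object) {
  n <- length(object@ids)
  if (length(object@sets) != n || length(object@traces) != n ||
      length(object@graphs) != n)
    return("ids, sets, traces and graphs must have equal length")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
    return("identifier sets must not contain duplicates")
  TRUE
})

setMethod("length", "SubstructureSets", function(x) length(x@ids))

setMethod("show", "SubstructureSets", function(object) {
  sizes <- lengths(object@sets)
  cat(sprintf(
    "SubstructureSets: %d compounds, %s unique identifiers overall\n",
    length(object@ids),
    format(length(unique(unlist(object@sets))))))
  cat(sprintf("  identifiers per compound: min %s / median %s / max %s\n",
              if (length(sizes)) min(sizes) else 0,
              if (length(sizes)) stats::median(sizes) else 0,
              if (length(sizes)) max(sizes) else 0))
  show(object@config)
})

setMethod("[", "SubstructureSets", function(x, i, j, ..., drop = TRUE) {
  idx <- seq_along(x@ids)[i]
  new("SubstructureSets", ids = x@ids[idx], sets = x@sets[idx],
      traces = x@traces[idx], graphs = x@graphs[idx], config = x@config)
})

#' Training vocabulary of substructure identifiers with support counts
#'
#' Aggregates per-compound identifier sets into the training vocabulary:
#' every identifier detected in at least one training compound together
#' with its support count, i.e. the number of distinct training compounds
#' containing it (presence, not multiplicity).
#'
#' @slot counts named numeric vector; names are identifier values (as
#'   decimal strings), values are support counts in \code{[1, n]}.
#' @slot nCompounds number of training compounds the vocabulary was built
#'   from.
#' @slot config the \code{EnumConfig} used for enumeration.
#' @export
setClass("SubstructureVocabulary",
  representation(
    counts = "numeric",
    nCompounds = "integer",
    config = "EnumConfig"
  )
)

setValidity("SubstructureVocabulary", function(object) {
  msg <- character(0)
  if (is.null(names(object@counts)) && length(object@counts))
    msg <- c(msg, "counts must be named by identifier")
  if (length(object@counts) &&
      (any(object@counts < 1) || any(object@counts > object@nCompounds)))
    msg <- c(msg, "support counts must lie in [1, nCompounds]")
  if (anyDuplicated(names(object@counts)))
    msg <- c(msg, "identifiers must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubstructureVocabulary", function(object) {
  cat(sprintf(
    "SubstructureVocabulary: m_T = %d unique substructures over n = %d compounds\n",
    length(object@counts), object@nCompounds))
  if (length(object@counts)) {
    cat(sprintf("  singleton fraction: %.1f%%\n",
                100 * mean(object@counts == 1)))
  }
  show(object@config)
})

#' Calibrated substructure-pooling operator
#'
#' The fitted state of one pooling operator. For hash-based folding the
#' state is just the fingerprint length (the fold is training-set
#' agnostic); for Sort & Slice it is the identifier list ordered by
#' training-set frequency rank; for filtering and mutual-information
#' maximisation it is the selected identifier list in a fixed position
#' order. Apply with \code{\link{poolFingerprints}}.
#'
#' @slot method one of \code{"folded"}, \code{"sort_slice"},
#'   \code{"filtered"}, \code{"mim"}.
#' @slot L fingerprint length.
#' @slot identifiers numeric vector mapping positions 1..length to
#'   identifier values (empty for \code{"folded"}); when shorter than
#'   \code{L}, fingerprints are zero-padded.
#' @slot counts support counts parallel to \code{identifiers} (may be
#'   empty for folded).
#' @slot seed integer seed consumed by any randomised calibration step.
#' @slot meta list of method-specific diagnostics (e.g. chi-squared
#'   p-values or mutual-information values of the selected identifiers).
#' @export
setClass("PoolerCalibration",
  representation(
    method = "character",
    L = "integer",
    identifiers = "numeric",
    counts = "numeric",
    seed = "integer",
    meta = "list"
  )
)

setValidity("PoolerCalibration", function(object) {
  msg <- character(0)
  if (!object@method %in% c("folded", "sort_slice", "filtered", "mim"))
    msg <- c(msg, "unknown pooling method")
  if (length(object@L) != 1L || object@L < 1L)
    msg <- c(msg, "L must be a positive integer")
  if (anyDuplicated(object@identifiers))
    msg <- c(msg, "identifier list must not contain duplicates")
  if (length(object@identifiers) > object@L)
    msg <- c(msg, "identifier list cannot be longer than L")
  if (object@method == "sort_slice" && length(object@counts)) {
    if (is.unsorted(rev(object@counts)))
      msg <- c(msg, "sort_slice support counts must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PoolerCalibration", function(object) {
  cat(sprintf("PoolerCalibration: method=%s, L=%d, %d identifiers%s\n",
              object@method, object@L, length(object@identifiers),
              if (length(object@identifiers) < object@L &&
                  object@method != "folded")
                sprintf(" (zero-padded to %d)", object@L) else ""))
})

#' Cross-validation split plan
#'
#' Fold assignments for repeated k-fold cross validation under a random,
#' stratified or Bemis-Murcko scaffold splitting scheme. Scaffold splits
#' guarantee that no scaffold string occurs in more than one fold.
#'
#' @slot scheme \code{"random"}, \code{"stratified"} or
#'   \code{"scaffold"}.
#' @slot nFolds number of folds (2 in the standard repeated 2-fold
#'   protocol).
#' @slot seeds integer vector of repetition seeds.
#' @slot assignments list (one element per seed) of integer vectors
#'   giving the fold index of every compound.
#' @export
setClass("SplitPlan",
  representation(
    scheme = "character",
    nFolds = "integer",
    seeds = "integer",
    assignments = "list"
  )
)

setValidity("SplitPlan", function(object) {
  msg <- character(0)
  if (!object@scheme %in% c("random", "stratified", "scaffold"))
    msg <- c(msg, "unknown split scheme")
  if (length(object@assignments) != length(object@seeds))
    msg <- c(msg, "one assignment vector per seed required")
  for (a in object@assignments)
    if (!all(sort(unique(a)) %in% seq_len(object@nFolds)))
      msg <- c(msg, "fold indices must lie in 1..nFolds")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %s, %d folds x %d seeds over %d compounds\n",
              object@scheme, object@nFolds, length(object@seeds),
              if (length(object@assignments))
                length(object@assignments[[1]]) else 0L))
})

#' Synthetic molecule-library specification
#'
#' Parameters of the grammar-based synthetic library generator: molecules
#' are composed as linear chains of self-contained SMILES fragments so
#' that every emitted SMILES is chemically valid by construction. Common
#' fragments are drawn with the given weights; a large pool of rare
#' decorations is sampled with small probability to reproduce the
#' heavy-tailed substructure-frequency distribution typical of chemical
#' datasets; an optional planted fragment (with an element unique to it)
#' carries a recoverable label signal.
#'
#' @slot nCompounds number of molecules to generate (>= 4).
#' @slot commonFragments,commonWeights fragment pool and sampling weights
#'   for the chain body.
#' @slot rareFragments pool of rare decorations.
#' @slot rareProb probability that a compound receives one rare
#'   decoration.
#' @slot chainRange integer range (min, max) of common fragments per
#'   chain.
#' @slot plantedFragment SMILES fragment carrying the planted signal
#'   (\code{""} for none).
#' @slot plantedProb probability that a compound contains the planted
#'   fragment.
#' @slot seed mandatory integer seed.
#' @export
setClass("FixtureSpec",
  representation(
    nCompounds = "integer",
    commonFragments = "character",
    commonWeights = "numeric",
    rareFragments = "character",
    rareProb = "numeric",
    chainRange = "integer",
    plantedFragment = "character",
    plantedProb = "numeric",
    seed = "integer"
  )
)

setValidity("FixtureSpec", function(object) {
  msg <- character(0)
  if (object@nCompounds < 4L)
    msg <- c(msg, "nCompounds must be at least 4")
  if (length(object@commonFragments) != length(object@commonWeights) ||
      !length(object@commonFragments))
    msg <- c(msg, "commonFragments and commonWeights must be non-empty and parallel")
  if (any(!is.finite(object@commonWeights)) || any(object@commonWeights < 0))
    msg <- c(msg, "weights must be finite and non-negative")
  if (object@rareProb < 0 || object@rareProb > 1 ||
      object@plantedProb < 0 || object@plantedProb > 1)
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(object@chainRange) != 2L || object@chainRange[1] < 1L ||
      object@chainRange[2] < object@chainRange[1])
    msg <- c(msg, "chainRange must be (min, max) with 1 <= min <= max")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a seed is mandatory")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(
    "FixtureSpec: n=%d, %d common + %d rare fragments, planted='%s' (p=%.2f), seed=%d\n",
    object@nCompounds, length(object@commonFragments),
    length(object@rareFragments), object@plantedFragment,
    object@plantedProb, object@seed))
})
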