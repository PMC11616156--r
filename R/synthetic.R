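# Grammar-based synthetic molecule libraries with planted substructure
# signal. Molecules are linear chains of self-contained SMILES
# fragments; because every fragment is attachable by plain
# concatenation, all emitted SMILES are valid without a rejection loop.

.DEFAULT_COMMON <- c("C", "CC", "CCC", "CO", "CN", "CCO", "C(C)C",
                     "C(=O)", "C(=O)N", "COC", "CNC", "C=C",
                     "c1ccccc1", "C1CCCCC1", "CCN")

# Every fragment is attachable at both ends: the first atom accepts a
# preceding bond and the last atom has a free valence for the next
# fragment (halogens and nitriles therefore hang off branches).
.DEFAULT_RARE <- c("C(C(F)(F)F)", "C(Cl)", "C(Br)", "C(I)", "C(C#N)",
                   "C(C)(C)C", "CC(Cl)C", "C(Cl)(Cl)C", "C(F)C",
                   "C#CC", "CC(Br)C", "C1CC1", "C1CCC1", "C1CCCC1",
                   "CC(C)O", "CN(C)C", "C(=O)OC", "CCCCCC", "CC(=C)C",
                   "C1CCOC1", "C1CCNC1", "C1CCOCC1", "C1CCNCC1",
                   "c1ccncc1", "c1occc1", "c1cccnc1", "CC(O)C",
                   "C(=O)OCC", "CC(N)C", "OCC(O)C", "C(=O)C(C)C",
                   "CCOCC", "CC=CC", "C1CCCCCC1", "CC(C)(C)O",
                   "CN(CC)C", "COCOC", "CC#CC", "CCC(C)N",
                   "C(c1ccccc1)C")

#' Construct a synthetic library specification
#'
#' Defaults emulate the heavy-tailed substructure-frequency distribution
#' of real chemical datasets: a small pool of common chain fragments
#' sampled with geometrically decaying weights, a large pool of rare
#' decorations each hit by only a few compounds (whose junction
#' environments produce singleton substructures), and an optional
#' planted fragment carrying a sulfur atom absent from the rest of the
#' grammar, so that its substructure support exactly matches the set of
#' compounds containing it.
#'
#' @param nCompounds library size (>= 4; default 100).
#' @param commonFragments,commonWeights chain-body fragment pool.
#' @param rareFragments rare decoration pool.
#' @param rareProb probability of one rare decoration per compound
#'   (default 0.7).
#' @param chainRange min/max number of common fragments per chain
#'   (default 3..6).
#' @param plantedFragment planted signal fragment; \code{""} disables
#'   (default \code{"C(SC)"}, a thiomethyl branch: the only sulfur
#'   source in the grammar, and positioned so that the sulfur atom
#'   environment is identical wherever the fragment sits in the chain).
#' @param plantedProb probability of carrying the planted fragment
#'   (default 0.5).
#' @param seed mandatory integer seed.
#' @return A \code{\link{FixtureSpec-class}}.
#' @export
fixtureSpec <- function(nCompounds = 100L,
                        commonFragments = .DEFAULT_COMMON,
                        commonWeights = 0.7^seq_along(commonFragments),
                        rareFragments = .DEFAULT_RARE,
                        rareProb = 0.7, chainRange = c(3L, 6L),
                        plantedFragment = "C(SC)", plantedProb = 0.5,
                        seed) {
  if (missing(seed)) stop("a seed is mandatory for a FixtureSpec")
  new("FixtureSpec", nCompounds = as.integer(nCompounds),
      commonFragments = commonFragments,
      commonWeights = as.numeric(commonWeights),
      rareFragments = rareFragments, rareProb = rareProb,
      chainRange = as.integer(chainRange),
      plantedFragment = plantedFragment, plantedProb = plantedProb,
      seed = as.integer(seed))
}

#' Generate a synthetic molecule library
#'
#' Composes \code{nCompounds} molecules by seeded sampling of fragment
#' chains. Every emitted SMILES is checked to parse; the fragment
#' composition of each compound is recorded in the \code{extra}
#' metadata (columns \code{fragments} and \code{planted}), which
#' \code{\link{plantLabels}} uses to attach label signal.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return An unlabelled \code{CompoundSet} (provenance
#'   \code{"synthetic"}).
#' @export
generateLibrary <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  n <- spec@nCompounds
  comps <- .withSeed(spec@seed, {
    lapply(seq_len(n), function(i) {
      k <- spec@chainRange[1] +
        sample.int(spec@chainRange[2] - spec@chainRange[1] + 1L, 1L) - 1L
      frags <- sample(spec@commonFragments, k, replace = TRUE,
                      prob = spec@commonWeights)
      if (length(spec@rareFragments) && stats::runif(1) < spec@rareProb) {
        rare <- sample(spec@rareFragments, 1L)
        pos <- sample.int(length(frags) + 1L, 1L) - 1L
        frags <- append(frags, rare, after = pos)
      }
      planted <- FALSE
      if (nzchar(spec@plantedFragment) &&
          stats::runif(1) < spec@plantedProb) {
        pos <- sample.int(length(frags) + 1L, 1L) - 1L
        frags <- append(frags, spec@plantedFragment, after = pos)
        planted <- TRUE
      }
      list(smiles = paste(frags, collapse = ""),
           fragments = paste(frags, collapse = ";"), planted = planted)
    })
  })
  smiles <- vapply(comps, `[[`, "", "smiles")
  canon <- .canonicalSmilesBatch(smiles)
  if (anyNA(canon))
    stop("fragment grammar produced invalid SMILES: ",
         paste(utils::head(smiles[is.na(canon)], 3), collapse = ", "))
  compoundSet(sprintf("synth_%04d", seq_len(n)), smiles,
              taskType = "unlabelled", provenance = "synthetic",
              extra = data.frame(
                fragments = vapply(comps, `[[`, "", "fragments"),
                planted = vapply(comps, `[[`, TRUE, "planted")))
}

#' Plant labels on a synthetic library
#'
#' Labels are a weighted sum of fragment presences plus seeded Gaussian
#' noise; for classification the noisy score is thresholded (default:
#' half the sum of positive weights, so that with a single unit-weight
#' fragment and no noise the label equals the fragment presence).
#'
#' @param x a \code{CompoundSet} from \code{\link{generateLibrary}}
#'   (needs the \code{fragments} metadata column).
#' @param weights named numeric vector: fragment SMILES -> weight.
#' @param noiseSd Gaussian noise standard deviation (default 0).
#' @param task \code{"regression"} or \code{"classification"}.
#' @param seed integer seed for the noise.
#' @param threshold classification threshold on the noisy score.
#' @return The \code{CompoundSet} with labels and task type set.
#' @export
plantLabels <- function(x, weights, noiseSd = 0,
                        task = c("regression", "classification"),
                        seed = 0L, threshold = NULL) {
  task <- match.arg(task)
  stopifnot(is(x, "CompoundSet"))
  if (!"fragments" %in% names(x@extra))
    stop("x has no fragment-composition metadata; generate it with ",
         "generateLibrary()")
  if (is.null(names(weights)) || !length(weights))
    stop("weights must be a named (fragment -> weight) vector")
  fragLists <- strsplit(x@extra$fragments, ";", fixed = TRUE)
  score <- vapply(fragLists, function(fr)
    sum(weights[names(weights) %in% fr]), 0)
  noisy <- .withSeed(seed,
    score + stats::rnorm(length(score), sd = noiseSd))
  if (task == "regression") {
    lab <- noisy
  } else {
    if (is.null(threshold)) threshold <- sum(pmax(weights, 0)) / 2
    lab <- as.integer(noisy > threshold)
  }
  new("CompoundSet", id = x@id, smiles = x@smiles, label = as.numeric(lab),
      taskType = task, provenance = x@provenance, extra = x@extra)
}
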