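#' @include AllClasses.R
NULL

#' Enumerate circular substructures
#'
#' Transforms compounds into their sets of hashed circular-substructure
#' identifiers: for every heavy atom and every radius \code{0..D/2}, the
#' iterated atom environment is reduced to a deterministic 32-bit integer
#' identifier (Morgan-style neighbourhood hashing over the configured
#' atomic invariants). Identifier sets use set semantics: an environment
#' occurring at several atoms of the same compound contributes one
#' identifier.
#'
#' @param x a \code{CompoundSet} or a character vector of SMILES strings.
#' @param config an \code{\link{enumConfig}} object.
#' @param ... unused.
#' @return A \code{\link{SubstructureSets-class}} object.
#' @export
setGeneric("enumerateSubstructures",
           function(x, config = enumConfig(), ...)
             standardGeneric("enumerateSubstructures"))

#' Build a training vocabulary with support counts
#'
#' @param x a \code{SubstructureSets} object for the training compounds.
#' @return A \code{\link{SubstructureVocabulary-class}}: the union of the
#'   per-compound identifier sets, each identifier with the number of
#'   distinct compounds containing it.
#' @export
setGeneric("buildVocabulary", function(x) standardGeneric("buildVocabulary"))

#' Calibrate a substructure-pooling operator
#'
#' Fits the training-set-dependent state of one of the four pooling
#' operators; see \code{\link{poolFingerprints}} for applying it.
#'
#' \describe{
#'   \item{\code{folded}}{hash-based folding; no training state beyond
#'     \code{L}.}
#'   \item{\code{sort_slice}}{orders the training vocabulary by support
#'     count (rank 1 = most frequent; at equal counts the larger
#'     identifier value takes the earlier rank) and keeps the first
#'     \code{min(L, m_T)} identifiers.}
#'   \item{\code{filtered}}{supervised selection: removes singleton-
#'     support identifiers at random, then randomly removes non-closed
#'     identifiers (those whose support equals that of another listed
#'     identifier isomorphic to a proper subgraph of their atom
#'     environment), then drops identifiers with the weakest chi-squared
#'     dependence on the (binarised) label until \code{L} remain.}
#'   \item{\code{mim}}{supervised selection: randomly collapses groups of
#'     identifiers with identical support sets to one member, then keeps
#'     the \code{L} identifiers with the highest plug-in mutual
#'     information with the (binarised) label.}
#' }
#'
#' @param x a \code{SubstructureSets} (required for \code{filtered} and
#'   \code{mim}) or a \code{SubstructureVocabulary} (sufficient for
#'   \code{folded} and \code{sort_slice}).
#' @param method one of \code{"folded"}, \code{"sort_slice"},
#'   \code{"filtered"}, \code{"mim"}.
#' @param L fingerprint length (positive integer).
#' @param labels training labels, required for the supervised methods;
#'   continuous labels are binarised at their median.
#' @param seed integer seed driving the randomised removal steps.
#' @param ... unused.
#' @return A \code{\link{PoolerCalibration-class}}.
#' @export
setGeneric("calibratePooler",
           function(x, method = c("folded", "sort_slice", "filtered", "mim"),
                    L, labels = NULL, seed = 0L, ...)
             standardGeneric("calibratePooler"))

#' Apply a calibrated pooling operator
#'
#' Maps identifier sets to binary fingerprints of length \code{L}. For
#' \code{folded}, bit \code{i} is set iff some identifier hashes to
#' \code{i} under the documented fold (identifier mod L). For the
#' selection-based methods, the bit at an identifier's position is set
#' iff that identifier is present; identifiers outside the calibrated
#' list (including substructures never seen in training) contribute
#' nothing, and positions map one-to-one to identifiers, so these
#' fingerprints are free of bit collisions.
#'
#' @param cal a \code{PoolerCalibration}.
#' @param x a \code{SubstructureSets}, or a single numeric identifier
#'   set.
#' @param ... unused.
#' @return An \code{n x L} binary integer matrix (rownames = compound
#'   ids), or a length-\code{L} vector for a single set.
#' @export
setGeneric("poolFingerprints",
           function(cal, x, ...) standardGeneric("poolFingerprints"))

#' @rdname CompoundSet-class
#' @param x,object a \code{CompoundSet}.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @rdname CompoundSet-class
#' @export
setGeneric("compoundSmiles", function(x) standardGeneric("compoundSmiles"))
#' @rdname CompoundSet-class
#' @export
setGeneric("compoundLabels", function(x) standardGeneric("compoundLabels"))
#' @rdname CompoundSet-class
#' @export
setGeneric("taskType", function(x) standardGeneric("taskType"))

#' @rdname SubstructureVocabulary-class
#' @param x a \code{SubstructureVocabulary}.
#' @export
setGeneric("vocabularySize", function(x) standardGeneric("vocabularySize"))
#' @rdname SubstructureVocabulary-class
#' @export
setGeneric("vocabularyCounts", function(x) standardGeneric("vocabularyCounts"))
#' @rdname SubstructureVocabulary-class
#' @export
setGeneric("vocabularyIdentifiers",
           function(x) standardGeneric("vocabularyIdentifiers"))

#' @rdname PoolerCalibration-class
#' @param x a \code{PoolerCalibration}.
#' @export
setGeneric("poolMethod", function(x) standardGeneric("poolMethod"))
#' @rdname PoolerCalibration-class
#' @export
setGeneric("poolLength", function(x) standardGeneric("poolLength"))
#' @rdname PoolerCalibration-class
#' @export
setGeneric("poolIdentifiers", function(x) standardGeneric("poolIdentifiers"))

setMethod("compoundIds", "CompoundSet", function(x) x@id)
setMethod("compoundSmiles", "CompoundSet", function(x) x@smiles)
setMethod("compoundLabels", "CompoundSet", function(x) x@label)
setMethod("taskType", "CompoundSet", function(x) x@taskType)

setMethod("vocabularySize", "SubstructureVocabulary",
          function(x) length(x@counts))
setMethod("vocabularyCounts", "SubstructureVocabulary", function(x) x@counts)
setMethod("vocabularyIdentifiers", "SubstructureVocabulary",
          function(x) as.numeric(names(x@counts)))

setMethod("poolMethod", "PoolerCalibration", function(x) x@method)
setMethod("poolLength", "PoolerCalibration", function(x) as.integer(x@L))
setMethod("poolIdentifiers", "PoolerCalibration", function(x) x@identifiers)

#' Substructure identifier sets
#'
#' @param x a \code{SubstructureSets}.
#' @return list of numeric identifier vectors, named by compound id.
#' @export
setGeneric("identifierSets", function(x) standardGeneric("identifierSets"))
setMethod("identifierSets", "SubstructureSets", function(x) {
  out <- x@sets
  names(out) <- x@ids
  out
})
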