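# Compound standardisation and dataset cleaning.

.ORGANIC_PARENT_ELEMS <- c("N", "O", "S", "C", "P", "Se")
.POS_H_ELEMS <- c("N", "O", "S", "P")

# Neutralise eligible charged atoms of a single-fragment SMILES by
# rewriting its atom tokens in place, then return the rewritten string
# (not yet canonicalised). Charge-separated groups where the neighbour
# carries the opposite charge (nitro, N-oxides, ...) are left untouched;
# quaternary nitrogens have no H to remove and stay charged.
.neutralizeFragment <- function(fragment, graph) {
  if (is.null(graph) || graph$natoms == 0L || !graph$annotated)
    return(fragment)
  if (all(graph$charge == 0L)) return(fragment)
  toks <- .tokenizeSmiles(fragment)
  toks <- toks[toks$elem != "H", , drop = FALSE]
  if (nrow(toks) != graph$natoms) return(fragment)
  newCharge <- graph$charge
  newH <- graph$nH
  changed <- logical(graph$natoms)
  for (a in seq_len(graph$natoms)) {
    chg <- graph$charge[a]
    if (chg == 0L) next
    nbrCharges <- graph$charge[graph$adj[[a]]]
    if (chg < 0L && graph$elem[a] %in% .ORGANIC_PARENT_ELEMS &&
        !any(nbrCharges > 0L)) {
      newH[a] <- newH[a] - chg
      newCharge[a] <- 0L
      changed[a] <- TRUE
    } else if (chg > 0L && graph$elem[a] %in% .POS_H_ELEMS &&
               graph$nH[a] >= chg && !any(nbrCharges < 0L)) {
      newH[a] <- newH[a] - chg
      newCharge[a] <- 0L
      changed[a] <- TRUE
    }
  }
  if (!any(changed)) return(fragment)
  out <- fragment
  for (a in rev(which(changed))) {
    elem <- graph$elem[a]
    if (graph$aromatic[a]) elem <- tolower(elem)
    tag <- c("", "@", "@@")[graph$chiral[a] + 1L]
    hPart <- if (newH[a] > 0L)
      paste0("H", if (newH[a] > 1L) newH[a] else "") else ""
    tok <- paste0("[", elem, tag, hPart, "]")
    out <- paste0(substr(out, 1L, toks$start[a] - 1L), tok,
                  substring(out, toks$end[a] + 1L))
  }
  out
}

#' Standardise and desalt SMILES strings
#'
#' Applies a pinned standardisation contract to each input: reject
#' strings that cannot be parsed into a molecule; strip isotopic
#' annotations; split multi-fragment records and drop counterions,
#' solvents and other carbon-free components; deduplicate identical
#' organic fragments; neutralise charged atoms where a proton can be
#' added or removed without touching charge-separated groups; and return
#' the canonical SMILES of the result. A record whose organic part still
#' consists of several distinct fragments (a genuine mixture) is returned
#' as a dot-separated string; \code{\link{cleanCompounds}} drops such
#' records. Tetrahedral stereo-annotations are preserved.
#'
#' @param smiles character vector of raw SMILES strings.
#' @return data.frame with columns \code{input}, \code{smiles}
#'   (canonical standardised SMILES or NA), \code{ok}, \code{reason}.
#' @examples
#' \donttest{
#' standardizeSmiles(c("CCO", "CC(=O)[O-].[Na+]", "C1CC1("))
#' }
#' @export
standardizeSmiles <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(input = as.character(smiles),
                    smiles = NA_character_,
                    ok = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  pre <- vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return("empty SMILES")
    if (!.smilesSyntaxOk(trimws(s))) return("invalid SMILES syntax")
    NA_character_
  }, "", USE.NAMES = FALSE)
  out$reason <- pre
  work <- which(is.na(pre))
  if (!length(work)) return(out)

  stripped <- .stripIsotopes(trimws(as.character(smiles)[work]))
  fragLists <- strsplit(stripped, ".", fixed = TRUE)
  badFrag <- vapply(fragLists, function(fr)
    !length(fr) || any(!vapply(fr, .smilesSyntaxOk, TRUE)), TRUE)
  out$reason[work[badFrag]] <- "invalid SMILES syntax"
  work <- work[!badFrag]
  fragLists <- fragLists[!badFrag]
  if (!length(work)) return(out)

  allFrags <- unique(unlist(fragLists))
  canon <- .canonicalSmilesBatch(allFrags)
  names(canon) <- allFrags

  parents <- rep(NA_character_, length(work))
  reason <- rep(NA_character_, length(work))
  multi <- rep(FALSE, length(work))
  canonVals <- unique(stats::na.omit(unname(canon)))
  fragInfo <- lapply(canonVals, function(s) {
    toks <- .tokenizeSmiles(s)
    if (is.null(toks)) return(list(carbon = FALSE, heavy = 0L))
    heavy <- toks$elem != "H"
    list(carbon = any(toks$elem == "C"), heavy = sum(heavy))
  })
  names(fragInfo) <- canonVals
  for (k in seq_along(work)) {
    cf <- canon[fragLists[[k]]]
    if (anyNA(cf)) { reason[k] <- "SMILES not parseable"; next }
    cf <- unique(unname(cf))
    cf <- cf[nzchar(cf)]
    if (!length(cf)) { reason[k] <- "SMILES not parseable"; next }
    hasC <- vapply(cf, function(s) fragInfo[[s]]$carbon, TRUE)
    organic <- sort(cf[hasC])
    if (!length(organic)) {
      # no carbon anywhere: keep the largest fragment
      heavy <- vapply(cf, function(s) fragInfo[[s]]$heavy, 0L)
      organic <- sort(cf[heavy == max(heavy)])[1]
    }
    parents[k] <- organic[1]
    if (length(organic) > 1L) {
      parents[k] <- paste(organic, collapse = ".")
      multi[k] <- TRUE
    }
  }

  todo <- which(!multi & !is.na(parents))
  if (length(todo)) {
    uniqParents <- unique(parents[todo])
    graphs <- .molFromSmilesBatch(uniqParents)
    neutral <- vapply(seq_along(uniqParents), function(i)
      .neutralizeFragment(uniqParents[i], graphs[[i]]), "")
    recanon <- .canonicalSmilesBatch(neutral)
    names(recanon) <- uniqParents
    for (k in todo) {
      cs <- recanon[[parents[k]]]
      if (is.na(cs) || !nzchar(cs)) reason[k] <- "standardisation failed"
      else parents[k] <- cs
    }
  }

  out$smiles[work] <- parents
  out$ok[work] <- !is.na(parents) & is.na(reason)
  out$reason[work] <- reason
  out$ok[is.na(out$smiles)] <- FALSE
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Clean a compound table
#'
#' Standardises and desalts every record (\code{\link{standardizeSmiles}}),
#' drops records that fail to parse, drops records whose standardised
#' SMILES still encodes several disconnected fragments, and collapses
#' duplicate canonical SMILES to a single record chosen uniformly at
#' random under \code{seed} (the dropped duplicate's label is discarded,
#' not averaged). The number of surviving records does not depend on the
#' seed; only the identity of the surviving duplicate does. Cleaning an
#' already-clean table is a no-op.
#'
#' @param x a \code{CompoundSet}.
#' @param seed integer seed for the duplicate choice.
#' @return A cleaned \code{CompoundSet}; the drop log (columns
#'   \code{id}, \code{input}, \code{reason}) is in
#'   \code{attr(, "dropLog")}.
#' @export
cleanCompounds <- function(x, seed = 0L) {
  stopifnot(is(x, "CompoundSet"))
  if (!length(x)) stop("empty input dataset")
  std <- standardizeSmiles(compoundSmiles(x))
  reason <- std$reason
  keep <- std$ok
  frag <- keep & grepl(".", std$smiles, fixed = TRUE)
  reason[frag] <- "disconnected fragments after standardisation"
  keep <- keep & !frag

  ids <- compoundIds(x)[keep]
  smi <- std$smiles[keep]
  lab <- compoundLabels(x)[keep]
  extra <- if (nrow(x@extra)) x@extra[keep, , drop = FALSE] else x@extra
  dup <- character(0)
  if (length(smi)) {
    groups <- split(seq_along(smi), smi)
    survivors <- .withSeed(seed, {
      vapply(groups[order(names(groups))], function(g)
        if (length(g) == 1L) g else g[sample.int(length(g), 1L)], 0L)
    })
    survivors <- sort(survivors)
    dup <- ids[setdiff(seq_along(smi), survivors)]
    ids <- ids[survivors]; smi <- smi[survivors]; lab <- lab[survivors]
    extra <- if (nrow(extra)) extra[survivors, , drop = FALSE] else extra
  }
  if (!length(ids)) stop("all records were rejected: empty dataset")

  logDf <- rbind(
    data.frame(id = compoundIds(x)[!keep],
               input = compoundSmiles(x)[!keep],
               reason = reason[!keep], stringsAsFactors = FALSE),
    data.frame(id = dup, input = rep(NA_character_, length(dup)),
               reason = rep("duplicate canonical SMILES", length(dup)),
               stringsAsFactors = FALSE))
  res <- new("CompoundSet", id = ids, smiles = smi, label = lab,
             taskType = x@taskType, provenance = x@provenance,
             extra = extra)
  attr(res, "dropLog") <- logDf
  res
}

#' Read a compound table from delimited text
#'
#' @param path CSV/TSV file path (delimiter inferred from the
#'   extension, or set \code{sep}).
#' @param smilesCol,labelCol,idCol column names; \code{labelCol} and
#'   \code{idCol} may be NULL (ids default to the row number).
#' @param taskType \code{"regression"}, \code{"classification"} or
#'   \code{"unlabelled"}.
#' @param provenance free-text source tag.
#' @param sep field separator; default inferred.
#' @return A \code{CompoundSet}.
#' @export
readCompoundTable <- function(path, smilesCol = "smiles", labelCol = NULL,
                              idCol = NULL, taskType = "unlabelled",
                              provenance = basename(path), sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (!smilesCol %in% names(df))
    stop("column '", smilesCol, "' not found in ", path)
  ids <- if (!is.null(idCol) && idCol %in% names(df))
    as.character(df[[idCol]]) else as.character(seq_len(nrow(df)))
  labels <- if (!is.null(labelCol) && labelCol %in% names(df))
    as.numeric(df[[labelCol]]) else rep(NA_real_, nrow(df))
  compoundSet(ids, df[[smilesCol]], labels, taskType = taskType,
              provenance = provenance)
}

#' Write a compound table as CSV
#'
#' @param x a \code{CompoundSet}.
#' @param path output path.
#' @export
writeCompoundTable <- function(x, path) {
  stopifnot(is(x, "CompoundSet"))
  df <- data.frame(id = compoundIds(x), smiles = compoundSmiles(x),
                   label = compoundLabels(x), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
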