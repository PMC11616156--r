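# The four substructure-pooling operators: hash-based folding,
# Sort & Slice, chi-squared filtering, and mutual-information
# maximisation.

#' Hash-based folding of an identifier set
#'
#' The classical ECFP vectorisation: every identifier is compressed onto
#' \code{1..L} by the documented fold \code{h(J) = (J mod L) + 1} and the
#' corresponding bit is set. Distinct substructures may collide on one
#' bit. The fold is training-set agnostic.
#'
#' @param x a numeric identifier set, or a \code{SubstructureSets}.
#' @param L fingerprint length (positive integer).
#' @return A binary vector of length \code{L}, or an \code{n x L} binary
#'   matrix for a \code{SubstructureSets}.
#' @examples
#' hashFold(c(5, 1029), 1024)[6]  # both identifiers fold onto bit 6
#' @export
hashFold <- function(x, L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be a positive integer")
  if (is(x, "SubstructureSets")) {
    v <- vapply(x@sets, .foldOne, integer(L), L = L)
    m <- if (L == 1L) matrix(v, ncol = 1L) else t(v)
    rownames(m) <- x@ids
    return(m)
  }
  .foldOne(as.numeric(x), L)
}

.foldOne <- function(set, L) {
  bits <- integer(L)
  if (length(set)) bits[unique(set %% L) + 1L] <- 1L
  bits
}

#' Binarise labels at their median
#'
#' Continuous labels are mapped to \code{{0, 1}} for the supervised
#' selection schemes: values at or below the median become 0, values
#' above it become 1. Labels already in \code{{0, 1}} are returned
#' unchanged.
#'
#' @param labels numeric vector.
#' @return integer vector of 0/1.
#' @export
binarizeLabels <- function(labels) {
  if (anyNA(labels)) stop("labels must not contain NA")
  if (all(labels %in% c(0, 1))) return(as.integer(labels))
  med <- stats::median(labels)
  as.integer(labels > med)
}

# 2x2 contingency of (binary label x feature presence) from a support
# index set.
.table2x2 <- function(supp, y, n) {
  n11 <- sum(y[supp])
  n10 <- length(supp) - n11
  pos <- sum(y)
  c(n00 = n - length(supp) - (pos - n11), n01 = pos - n11,
    n10 = n10, n11 = n11)
}

.chi2pTable <- function(tab) {
  m <- matrix(tab, 2, 2)           # rows: feature 0/1, cols: label 0/1
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) return(1)
  e <- outer(rs, cs) / n
  stat <- sum((m - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

.mi2x2 <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- c(p[1] + p[2], p[3] + p[4])   # feature 0/1
  py <- c(p[1] + p[3], p[2] + p[4])   # label 0/1
  plogp <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  plogp(px) + plogp(py) - plogp(p)
}

# --- calibrations -----------------------------------------------------------

.calFolded <- function(L, config) {
  new("PoolerCalibration", method = "folded", L = as.integer(L),
      identifiers = numeric(0), counts = numeric(0), seed = 0L,
      meta = list())
}

.calSortSlice <- function(counts, L) {
  ids <- as.numeric(names(counts))
  cnt <- as.numeric(counts)
  # rank 1 = most frequent; at equal counts the larger identifier value
  # takes the earlier rank (the identifier order breaks ties)
  ord <- order(-cnt, -ids)
  keep <- ord[seq_len(min(L, length(ids)))]
  new("PoolerCalibration", method = "sort_slice", L = as.integer(L),
      identifiers = ids[keep], counts = cnt[keep], seed = 0L,
      meta = list(mT = length(ids)))
}

.repOccurrence <- function(sets, traces, supports, key) {
  comp <- supports[[key]][1]
  tr <- traces[[comp]]
  row <- which(.idKey(tr$id) == key)[1]
  list(compound = comp, atom = tr$atom[row], radius = tr$radius[row])
}

# Does environment i strictly contain an isomorphic copy of
# environment j? Fast path: same compound and centre atom with nested
# radii; fall back to VF2 monomorphism with vertex/edge colours.
.envContains <- function(envs, occs, i, j) {
  oi <- occs[[i]]; oj <- occs[[j]]
  gi <- envs[[i]]; gj <- envs[[j]]
  ni <- igraph::vcount(gi); nj <- igraph::vcount(gj)
  ei <- igraph::ecount(gi); ej <- igraph::ecount(gj)
  if (nj > ni || ej > ei || (nj == ni && ej == ei)) return(FALSE)
  if (oi$compound == oj$compound && oi$atom == oj$atom &&
      oj$radius < oi$radius) return(TRUE)
  if (ej == 0L)                     # single-atom environment
    return(igraph::vertex_attr(gj, "color") %in%
           igraph::vertex_attr(gi, "color"))
  isTRUE(igraph::subgraph_isomorphic(gj, gi, method = "vf2"))
}

.calFiltered <- function(x, labels, L, seed) {
  sets <- x@sets
  n <- length(sets)
  if (length(labels) != n)
    stop("labels must have one entry per training compound")
  y <- binarizeLabels(labels)
  if (length(unique(y)) < 2L)
    stop("degenerate labels: chi-squared scores are undefined for a ",
         "constant label vector")
  supports <- .supportSets(sets)
  keys <- names(supports)
  ids <- as.numeric(keys)
  m <- length(ids)
  L <- as.integer(L)
  remaining <- rep(TRUE, m)

  if (L < m) {
    .withSeed(seed, {
      # Step 1: drop singleton-support identifiers in random order
      singles <- which(lengths(supports) == 1L)
      if (length(singles)) {
        rmOrder <- singles[sample.int(length(singles))]
        nRemove <- min(length(singles), m - L)
        remaining[rmOrder[seq_len(nRemove)]] <- FALSE
      }
      # Step 2: drop non-closed identifiers in random order
      if (sum(remaining) > L) {
        suppKey <- vapply(supports, paste, "", collapse = ",")
        envCache <- new.env(parent = emptyenv())
        occs <- vector("list", m)
        getEnv <- function(k) {
          ck <- as.character(k)
          if (is.null(envCache[[ck]])) {
            occ <- .repOccurrence(sets, x@traces, supports, keys[k])
            occs[[k]] <<- occ
            envCache[[ck]] <- .environmentGraph(
              x@graphs[[occ$compound]], occ$atom, occ$radius)
          }
          envCache[[ck]]
        }
        groups <- split(which(remaining), suppKey[remaining])
        groups <- groups[lengths(groups) > 1L]
        for (grp in groups) for (k in grp) { getEnv(k) }
        nonClosedIn <- function(grp) {
          live <- grp[remaining[grp]]
          if (length(live) < 2L) return(integer(0))
          envs <- lapply(seq_len(m), function(k)
            envCache[[as.character(k)]])
          bad <- vapply(live, function(i)
            any(vapply(setdiff(live, i), function(j)
              .envContains(envs, occs, i, j), TRUE)), TRUE)
          live[bad]
        }
        repeat {
          if (sum(remaining) <= L) break
          cand <- unlist(lapply(groups, nonClosedIn))
          if (!length(cand)) break
          remaining[cand[sample.int(length(cand), 1L)]] <- FALSE
        }
      }
    })
    # Step 3: chi-squared ranking; remove the weakest features first
    if (sum(remaining) > L) {
      live <- which(remaining)
      pvals <- vapply(live, function(k)
        .chi2pTable(.table2x2(supports[[k]], y, n)), 0)
      rmOrder <- live[order(-pvals, ids[live])]
      remaining[rmOrder[seq_len(sum(remaining) - L)]] <- FALSE
    }
  }
  sel <- which(remaining)
  selIds <- sort(ids[sel])
  selKeys <- .idKey(selIds)
  p <- vapply(selKeys, function(k)
    .chi2pTable(.table2x2(supports[[k]], y, n)), 0, USE.NAMES = FALSE)
  new("PoolerCalibration", method = "filtered", L = L,
      identifiers = selIds,
      counts = lengths(supports)[selKeys],
      seed = as.integer(seed), meta = list(mT = m, pvalues = p))
}

.calMIM <- function(x, labels, L, seed) {
  sets <- x@sets
  n <- length(sets)
  if (length(labels) != n)
    stop("labels must have one entry per training compound")
  y <- binarizeLabels(labels)
  degenerate <- length(unique(y)) < 2L
  if (degenerate)
    warning("degenerate labels: mutual information is 0 for every ",
            "feature; selection falls back to the identifier order")
  supports <- .supportSets(sets)
  keys <- names(supports)
  ids <- as.numeric(keys)
  m <- length(ids)
  L <- as.integer(L)
  remaining <- rep(TRUE, m)

  if (L < m) {
    # Step 1: collapse identifier groups with identical support sets
    .withSeed(seed, {
      suppKey <- vapply(supports, paste, "", collapse = ",")
      groups <- split(seq_len(m), suppKey)
      groups <- groups[lengths(groups) > 1L]
      repeat {
        if (sum(remaining) <= L) break
        sizes <- vapply(groups, function(g) sum(remaining[g]), 0L)
        open <- which(sizes > 1L)
        if (!length(open)) break
        w <- sizes[open] * (sizes[open] - 1L) / 2
        gi <- open[sample.int(length(open), 1L, prob = w)]
        live <- groups[[gi]][remaining[groups[[gi]]]]
        pair <- live[sample.int(length(live), 2L)]
        remaining[pair[sample.int(2L, 1L)]] <- FALSE
      }
    })
    # Step 2: keep the L features with the highest mutual information
    if (sum(remaining) > L) {
      live <- which(remaining)
      mi <- if (degenerate) rep(0, length(live)) else
        vapply(live, function(k)
          .mi2x2(.table2x2(supports[[k]], y, n)), 0)
      rmOrder <- live[order(mi, ids[live])]
      remaining[rmOrder[seq_len(sum(remaining) - L)]] <- FALSE
    }
  }
  sel <- which(remaining)
  selIds <- sort(ids[sel])
  selKeys <- .idKey(selIds)
  mi <- vapply(selKeys, function(k)
    .mi2x2(.table2x2(supports[[k]], y, n)), 0, USE.NAMES = FALSE)
  new("PoolerCalibration", method = "mim", L = L,
      identifiers = selIds,
      counts = lengths(supports)[selKeys],
      seed = as.integer(seed), meta = list(mT = m, mi = mi))
}

#' @rdname calibratePooler
#' @export
setMethod("calibratePooler", "SubstructureVocabulary",
  function(x, method = c("folded", "sort_slice", "filtered", "mim"),
           L, labels = NULL, seed = 0L, ...) {
    method <- match.arg(method)
    if (missing(L) || L < 1L) stop("L must be a positive integer")
    switch(method,
      folded = .calFolded(L, x@config),
      sort_slice = .calSortSlice(x@counts, L),
      stop("method '", method,
           "' needs per-compound supports; calibrate from a ",
           "SubstructureSets object"))
  })

#' @rdname calibratePooler
#' @export
setMethod("calibratePooler", "SubstructureSets",
  function(x, method = c("folded", "sort_slice", "filtered", "mim"),
           L, labels = NULL, seed = 0L, ...) {
    method <- match.arg(method)
    if (missing(L) || L < 1L) stop("L must be a positive integer")
    switch(method,
      folded = .calFolded(L, x@config),
      sort_slice = .calSortSlice(buildVocabulary(x)@counts, L),
      filtered = .calFiltered(x, labels, L, seed),
      mim = .calMIM(x, labels, L, seed))
  })

.poolOne <- function(cal, set) {
  if (cal@method == "folded") return(.foldOne(set, cal@L))
  bits <- integer(cal@L)
  pos <- match(set, cal@identifiers)
  pos <- pos[!is.na(pos)]
  bits[pos] <- 1L
  bits
}

#' @rdname poolFingerprints
#' @export
setMethod("poolFingerprints",
  signature(cal = "PoolerCalibration", x = "SubstructureSets"),
  function(cal, x, ...) {
    v <- vapply(x@sets, .poolOne, integer(cal@L), cal = cal)
    m <- if (cal@L == 1L) matrix(v, ncol = 1L) else t(v)
    rownames(m) <- x@ids
    colnames(m) <- if (cal@method == "folded") NULL else
      c(.idKey(cal@identifiers),
        rep("pad", cal@L - length(cal@identifiers)))
    m
  })

#' @rdname poolFingerprints
#' @export
setMethod("poolFingerprints",
  signature(cal = "PoolerCalibration", x = "numeric"),
  function(cal, x, ...) .poolOne(cal, x))

#' Export / import a pooling calibration as JSON
#'
#' The calibration is written as plain JSON so that external tools can
#' audit which substructure identifier owns each fingerprint position
#' (the interpretability guarantee of collision-free pooling).
#'
#' @param cal a \code{PoolerCalibration}.
#' @param path JSON file path.
#' @return \code{writeCalibration} returns the path invisibly;
#'   \code{readCalibration} returns a \code{PoolerCalibration}.
#' @export
writeCalibration <- function(cal, path) {
  stopifnot(is(cal, "PoolerCalibration"))
  obj <- list(method = cal@method, L = cal@L,
              identifiers = cal@identifiers,
              counts = as.numeric(cal@counts), seed = cal@seed,
              meta = cal@meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PoolerCalibration", method = obj$method, L = as.integer(obj$L),
      identifiers = as.numeric(obj$identifiers),
      counts = as.numeric(obj$counts), seed = as.integer(obj$seed),
      meta = as.list(obj$meta))
}
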