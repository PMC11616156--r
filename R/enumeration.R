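# Circular-substructure enumeration: iterated Morgan-style neighbourhood
# hashing of atom environments into 32-bit integer identifiers.

.HASH_MOD <- 2^32

# Canonical string key for a 32-bit identifier stored as double.
.idKey <- function(id) sprintf("%.0f", id)

# Deterministic 32-bit polynomial hash of a non-negative integer tuple.
# Base-31 Horner scheme; all intermediates stay below 2^38, well inside
# exact double precision, so the result is platform-independent.
.hash32 <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + x) %% .HASH_MOD
  h
}

# Initial atomic invariants, one row per heavy atom.
.atomInvariants <- function(graph, config) {
  n <- graph$natoms
  if (n == 0L) return(matrix(numeric(0), nrow = 0, ncol = 1))
  heavyDeg <- lengths(graph$adj)
  if (config@invariants == "standard") {
    inv <- cbind(graph$Z, heavyDeg, graph$nH, graph$charge + 8L,
                 as.integer(graph$inRing))
  } else {
    inv <- cbind(.isDonor(graph), .isAcceptor(graph),
                 .isNegIonizable(graph), .isPosIonizable(graph),
                 as.integer(graph$aromatic), .isHalogen(graph))
  }
  if (config@useChirality) inv <- cbind(inv, graph$chiral)
  inv
}

# Rule-based pharmacophoric invariants (FCFP-style). These are
# deliberately simple structural rules, documented in the methods
# vignette; they seed the environment hashing, so internal consistency
# matters more than pharmacological nuance.
.isHalogen <- function(graph)
  as.integer(graph$elem %in% c("F", "Cl", "Br", "I"))

.isDonor <- function(graph)
  as.integer(graph$elem %in% c("N", "O") & graph$nH > 0L)

.isAcceptor <- function(graph)
  as.integer((graph$elem == "O" & graph$charge <= 0L) |
             (graph$elem == "N" & graph$charge <= 0L &
              lengths(graph$adj) + graph$nH < 4L))

# Acidic oxygens (carboxylic/sulfonic/phosphoric OH) or any negatively
# charged atom.
.isNegIonizable <- function(graph) {
  res <- graph$charge < 0L
  oh <- which(graph$elem == "O" & graph$nH > 0L)
  for (a in oh) {
    for (nb in graph$adj[[a]]) {
      if (!graph$elem[nb] %in% c("C", "S", "P")) next
      others <- setdiff(graph$adj[[nb]], a)
      dblO <- any(vapply(others, function(o) {
        b <- graph$bonds[graph$adjBond[[nb]][match(o, graph$adj[[nb]])], ]
        graph$elem[o] == "O" && b$order == 2L
      }, TRUE))
      if (dblO) { res[a] <- TRUE; break }
    }
  }
  as.integer(res)
}

# Basic amines (non-aromatic N with H, no adjacent carbonyl) or any
# positively charged atom.
.isPosIonizable <- function(graph) {
  res <- graph$charge > 0L
  ns <- which(graph$elem == "N" & !graph$aromatic & graph$nH > 0L &
              graph$charge == 0L)
  for (a in ns) {
    amide <- FALSE
    for (nb in graph$adj[[a]]) {
      if (graph$elem[nb] != "C") next
      others <- setdiff(graph$adj[[nb]], a)
      for (o in others) {
        b <- graph$bonds[graph$adjBond[[nb]][match(o, graph$adj[[nb]])], ]
        if (graph$elem[o] %in% c("O", "S") && b$order == 2L) amide <- TRUE
      }
    }
    if (!amide) res[a] <- TRUE
  }
  as.integer(res)
}

# Enumerate identifiers for one molecular graph. Returns a data.frame
# trace (id, atom, radius); the identifier set is unique(trace$id).
.enumerateGraph <- function(graph, config) {
  nRadii <- config@maxDiameter %/% 2L
  n <- graph$natoms
  if (n == 0L)
    return(data.frame(id = numeric(0), atom = integer(0),
                      radius = integer(0)))
  inv <- .atomInvariants(graph, config)
  ids <- vapply(seq_len(n), function(a) .hash32(c(1, inv[a, ])), 0)
  trace <- data.frame(id = ids, atom = seq_len(n), radius = 0L)
  if (nRadii > 0L) {
    bondCode <- graph$bonds$code
    for (r in seq_len(nRadii)) {
      newIds <- numeric(n)
      for (a in seq_len(n)) {
        nbrs <- graph$adj[[a]]
        if (length(nbrs)) {
          pairs <- cbind(bondCode[graph$adjBond[[a]]], ids[nbrs])
          ord <- order(pairs[, 1], pairs[, 2])
          flat <- as.vector(t(pairs[ord, , drop = FALSE]))
        } else flat <- numeric(0)
        newIds[a] <- .hash32(c(2, r, ids[a], flat))
      }
      ids <- newIds
      trace <- rbind(trace,
                     data.frame(id = ids, atom = seq_len(n), radius = r))
    }
  }
  trace
}

#' @rdname enumerateSubstructures
#' @export
setMethod("enumerateSubstructures", "character",
  function(x, config = enumConfig(), ...) {
    ids <- names(x)
    if (is.null(ids)) ids <- as.character(seq_along(x))
    # canonicalise first: OpenBabel's canonical SMILES makes enumeration
    # invariant to the input atom numbering and fixes one Kekule form
    canon <- .canonicalSmilesBatch(x)
    if (anyNA(canon))
      stop("invalid SMILES at position(s): ",
           paste(which(is.na(canon)), collapse = ", "))
    graphs <- .molFromSmilesBatch(canon)
    bad <- vapply(graphs, is.null, TRUE)
    if (any(bad))
      stop("unparseable SMILES at position(s): ",
           paste(which(bad), collapse = ", "))
    traces <- lapply(graphs, .enumerateGraph, config = config)
    sets <- lapply(traces, function(tr) sort(unique(tr$id)))
    new("SubstructureSets", ids = ids, sets = sets, traces = traces,
        graphs = graphs, config = config)
  })

#' @rdname enumerateSubstructures
#' @export
setMethod("enumerateSubstructures", "CompoundSet",
  function(x, config = enumConfig(), ...) {
    smi <- compoundSmiles(x)
    names(smi) <- compoundIds(x)
    enumerateSubstructures(smi, config = config, ...)
  })

#' @rdname buildVocabulary
#' @export
setMethod("buildVocabulary", "SubstructureSets", function(x) {
  if (!length(x@sets)) stop("no compounds to build a vocabulary from")
  allIds <- unlist(x@sets, use.names = FALSE)
  tab <- table(.idKey(allIds))
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  new("SubstructureVocabulary", counts = counts,
      nCompounds = length(x@sets), config = x@config)
})

# Support sets: identifier -> sorted integer vector of compound indices.
.supportSets <- function(sets) {
  n <- length(sets)
  idvec <- unlist(sets, use.names = FALSE)
  comp <- rep(seq_len(n), lengths(sets))
  split(comp, .idKey(idvec))
}

# Binary presence column of one identifier over the compounds.
.featureColumn <- function(sets, id, n = length(sets)) {
  col <- integer(n)
  for (i in seq_len(n)) if (id %in% sets[[i]]) col[i] <- 1L
  col
}

# Atom environment of (compound graph, centre atom, radius) as an igraph
# with atom-invariant vertex colours and bond-order edge colours. The
# environment contains every atom within graph distance `radius` of the
# centre and every bond with at least one endpoint strictly inside.
.environmentGraph <- function(graph, atom, radius) {
  dist <- rep(Inf, graph$natoms)
  dist[atom] <- 0
  frontier <- atom
  d <- 0
  while (length(frontier) && d < radius) {
    d <- d + 1
    nxt <- unique(unlist(graph$adj[frontier]))
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  atoms <- which(dist <= radius)
  b <- graph$bonds
  keep <- which((dist[b$a1] <= radius - 1 & dist[b$a2] <= radius) |
                (dist[b$a2] <= radius - 1 & dist[b$a1] <= radius))
  remap <- integer(graph$natoms)
  remap[atoms] <- seq_along(atoms)
  g <- igraph::make_empty_graph(n = length(atoms), directed = FALSE)
  vcol <- graph$Z[atoms] * 100 + graph$nH[atoms] * 10 +
    (graph$charge[atoms] + 4)
  g <- igraph::set_vertex_attr(g, "color", value = vcol)
  if (length(keep)) {
    el <- rbind(remap[b$a1[keep]], remap[b$a2[keep]])
    g <- igraph::add_edges(g, as.vector(el),
                           attr = list(color = b$code[keep]))
  }
  g
}
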