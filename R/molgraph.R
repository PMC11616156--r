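# Internal molecular-graph layer.
#
# SMILES parsing, canonicalisation and SDF interconversion are delegated
# to OpenBabel (via ChemmineOB/ChemmineR). On top of the parsed
# connection table this file derives everything enumeration needs: ring
# membership (bridge detection on the heavy-atom graph), aromaticity
# (read off OpenBabel's canonical SMILES, which writes aromatic atoms in
# lowercase), per-atom hydrogen counts (explicit-H parse), formal
# charges, and a tetrahedral chirality tag taken from the @/@@
# annotations of the canonical SMILES.
#
# Alignment contract: OpenBabel emits SDF atoms in SMILES token order
# (added hydrogens last). Every parse asserts that the heavy-atom
# elements of the SDF match the atom tokens of the source SMILES; on
# mismatch the aromatic/chiral annotations are dropped for that molecule
# rather than silently misassigned.

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
  "Po", "At", "Rn")

.atomicNumber <- function(elem) {
  z <- match(elem, .ELEMENTS)
  z[is.na(z)] <- 0L
  z
}

.noOptions <- function() data.frame(names = character(0), args = character(0))

.obConvert <- function(from, to, text, addH = FALSE) {
  opts <- if (addH) data.frame(names = "h", args = "") else .noOptions()
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, source = text, options = opts),
    error = function(e) "")
  out
}

# --- SMILES text utilities --------------------------------------------------

.smilesSyntaxOk <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depthP <- 0L; depthB <- 0L
  for (ch in chars) {
    if (ch == "(") depthP <- depthP + 1L
    else if (ch == ")") depthP <- depthP - 1L
    else if (ch == "[") depthB <- depthB + 1L
    else if (ch == "]") depthB <- depthB - 1L
    if (depthP < 0L || depthB < 0L || depthB > 1L) return(FALSE)
  }
  depthP == 0L && depthB == 0L
}

.stripIsotopes <- function(s) gsub("\\[[0-9]+", "[", s)

# Scan a SMILES string and return one row per atom token, in writing
# order. Not a structural parser: bonds/rings are ignored; only element,
# aromatic case, chirality tag and (for bracket atoms) H count and charge
# are extracted, plus the character span of the token for rewriting.
.tokenizeSmiles <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  rows <- list()
  i <- 1L
  twoLetter <- c("Cl", "Br")
  single <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromaticSingle <- c("b", "c", "n", "o", "p", "s")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket in SMILES: ", s)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body,
        regexec("^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2})(TH[12])?(H[0-9]*)?([+-][0-9]*|\\+*|-*)", body))[[1]]
      elemRaw <- m[3]
      chiral <- nchar(m[4])
      hPart <- m[6]
      hcount <- if (is.na(hPart) || !nzchar(hPart)) 0L
        else if (hPart == "H") 1L else as.integer(sub("H", "", hPart))
      cPart <- m[7]
      charge <- 0L
      if (nzchar(cPart)) {
        if (grepl("^[+-][0-9]+$", cPart))
          charge <- as.integer(cPart)
        else
          charge <- (nchar(cPart)) *
            (if (substr(cPart, 1, 1) == "+") 1L else -1L)
      }
      aromatic <- substr(elemRaw, 1, 1) %in% letters
      elem <- paste0(toupper(substr(elemRaw, 1, 1)),
                     substring(elemRaw, 2))
      rows[[length(rows) + 1L]] <- list(elem = elem, aromatic = aromatic,
        chiral = chiral, hcount = hcount, charge = charge,
        start = i, end = j, bracket = TRUE)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% twoLetter) {
      rows[[length(rows) + 1L]] <- list(elem = paste0(ch, chars[i + 1L]),
        aromatic = FALSE, chiral = 0L, hcount = NA_integer_, charge = 0L,
        start = i, end = i + 1L, bracket = FALSE)
      i <- i + 2L
    } else if (ch %in% single) {
      rows[[length(rows) + 1L]] <- list(elem = ch, aromatic = FALSE,
        chiral = 0L, hcount = NA_integer_, charge = 0L,
        start = i, end = i, bracket = FALSE)
      i <- i + 1L
    } else if (ch %in% aromaticSingle) {
      rows[[length(rows) + 1L]] <- list(elem = toupper(ch), aromatic = TRUE,
        chiral = 0L, hcount = NA_integer_, charge = 0L,
        start = i, end = i, bracket = FALSE)
      i <- i + 1L
    } else if (ch == "%") {
      i <- i + 3L                     # two-digit ring closure
    } else {
      i <- i + 1L                     # bond symbols, digits, parens, dots
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# --- SDF parsing ------------------------------------------------------------

.CHARGE_CODES <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                   `5` = -1L, `6` = -2L, `7` = -3L)

# Parse multi-record SDF text into per-title atom/bond tables using
# ChemmineR. Returns a named list: title -> list(atoms, bonds).
.parseSDFText <- function(sdftext) {
  if (!nzchar(sdftext)) return(list())
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdftext, tf)
  sdfs <- suppressWarnings(suppressMessages(ChemmineR::read.SDFset(tf)))
  if (length(sdfs) == 0L) return(list())
  titles <- ChemmineR::sdfid(sdfs)
  out <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    ab <- ChemmineR::atomblock(sdfs[[k]])
    bb <- ChemmineR::bondblock(sdfs[[k]])
    elem <- sub("_[0-9]+$", "", rownames(ab))
    chgcode <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
    charge <- unname(.CHARGE_CODES[as.character(chgcode)])
    charge[is.na(charge)] <- 0L
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L)
      data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
    else
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    out[[k]] <- list(atoms = data.frame(elem = elem, charge = charge,
                                        stringsAsFactors = FALSE),
                     bonds = bonds)
  }
  names(out) <- titles
  out
}

# --- graph construction -----------------------------------------------------

.emptyGraph <- function(smiles) {
  list(natoms = 0L, elem = character(0), Z = integer(0),
       charge = integer(0), nH = integer(0), inRing = logical(0),
       aromatic = logical(0), chiral = integer(0),
       bonds = data.frame(a1 = integer(0), a2 = integer(0),
                          order = integer(0), code = integer(0),
                          inRing = logical(0)),
       adj = list(), smiles = smiles, annotated = TRUE)
}

.buildMolGraph <- function(rec, smiles) {
  elemAll <- rec$atoms$elem
  heavy <- which(elemAll != "H")
  if (!length(heavy)) return(.emptyGraph(smiles))
  remap <- integer(length(elemAll))
  remap[heavy] <- seq_along(heavy)
  nh <- length(heavy)
  bonds <- rec$bonds
  isH1 <- elemAll[bonds$a1] == "H"
  isH2 <- elemAll[bonds$a2] == "H"
  nH <- integer(nh)
  hb <- bonds[xor(isH1, isH2), , drop = FALSE]
  if (nrow(hb)) {
    heavyEnd <- ifelse(elemAll[hb$a1] == "H", hb$a2, hb$a1)
    tb <- table(remap[heavyEnd])
    nH[as.integer(names(tb))] <- as.integer(tb)
  }
  bb <- bonds[!isH1 & !isH2, , drop = FALSE]
  bdf <- data.frame(a1 = remap[bb$a1], a2 = remap[bb$a2],
                    order = bb$order)
  inRingBond <- rep(FALSE, nrow(bdf))
  if (nrow(bdf)) {
    g <- igraph::graph_from_edgelist(as.matrix(bdf[, c("a1", "a2")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < nh)
      g <- igraph::add_vertices(g, nh - igraph::vcount(g))
    br <- igraph::bridges(g)
    inRingBond <- !(seq_len(nrow(bdf)) %in% as.integer(br))
  }
  bdf$inRing <- inRingBond
  inRingAtom <- rep(FALSE, nh)
  if (any(inRingBond)) {
    ringAtoms <- unique(c(bdf$a1[inRingBond], bdf$a2[inRingBond]))
    inRingAtom[ringAtoms] <- TRUE
  }
  adj <- rep(list(integer(0)), nh)
  adjBond <- rep(list(integer(0)), nh)
  for (b in seq_len(nrow(bdf))) {
    i <- bdf$a1[b]; j <- bdf$a2[b]
    adj[[i]] <- c(adj[[i]], j); adjBond[[i]] <- c(adjBond[[i]], b)
    adj[[j]] <- c(adj[[j]], i); adjBond[[j]] <- c(adjBond[[j]], b)
  }
  elem <- elemAll[heavy]
  toks <- .tokenizeSmiles(smiles)
  toksHeavy <- if (!is.null(toks)) toks[toks$elem != "H", , drop = FALSE]
               else toks
  annotated <- !is.null(toksHeavy) && nrow(toksHeavy) == nh &&
    all(toksHeavy$elem == elem)
  aromatic <- rep(FALSE, nh)
  chiral <- rep(0L, nh)
  if (annotated) {
    aromatic <- toksHeavy$aromatic
    chiral <- toksHeavy$chiral
  }
  bdf$code <- ifelse(bdf$inRing & aromatic[bdf$a1] & aromatic[bdf$a2],
                     4L, bdf$order)
  list(natoms = nh, elem = elem, Z = .atomicNumber(elem),
       charge = rec$atoms$charge[heavy], nH = nH,
       inRing = inRingAtom, aromatic = aromatic, chiral = chiral,
       bonds = bdf, adj = adj, adjBond = adjBond,
       smiles = smiles, annotated = annotated)
}

# Batch-parse SMILES strings into molecular graphs. Returns a list the
# length of `smiles`; failed records are NULL with attribute "reason".
.molFromSmilesBatch <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  ok <- vapply(smiles, .smilesSyntaxOk, TRUE, USE.NAMES = FALSE)
  reasons <- rep(NA_character_, n)
  reasons[!ok] <- "invalid SMILES syntax"
  if (any(ok)) {
    titles <- paste0("m", which(ok))
    src <- paste0(smiles[ok], " ", titles, "\n", collapse = "")
    sdftext <- .obConvert("SMI", "SDF", src, addH = TRUE)
    recs <- .parseSDFText(sdftext)
    for (j in seq_along(which(ok))) {
      i <- which(ok)[j]
      rec <- recs[[paste0("m", i)]]
      if (is.null(rec)) {
        reasons[i] <- "SMILES not parseable by OpenBabel"
      } else {
        out[[i]] <- .buildMolGraph(rec, smiles[i])
      }
    }
  }
  attr(out, "reasons") <- reasons
  out
}

# Batch canonicalisation; NA for unparseable records.
.canonicalSmilesBatch <- function(smiles) {
  n <- length(smiles)
  res <- rep(NA_character_, n)
  ok <- vapply(smiles, .smilesSyntaxOk, TRUE, USE.NAMES = FALSE)
  if (!any(ok)) return(res)
  titles <- paste0("m", which(ok))
  src <- paste0(smiles[ok], " ", titles, "\n", collapse = "")
  out <- .obConvert("SMI", "CAN", src)
  if (!nzchar(out)) return(res)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    parts <- strsplit(ln, "[\t ]+")[[1]]
    if (length(parts) >= 2) {
      idx <- suppressWarnings(as.integer(sub("^m", "", parts[2])))
      if (!is.na(idx) && nzchar(parts[1])) res[idx] <- parts[1]
    }
  }
  res
}

# --- V2000 writing (scaffolds and environment export) -----------------------

.LEGACY_CHARGE <- function(chg) {
  code <- integer(length(chg))
  code[chg == 3] <- 1L; code[chg == 2] <- 2L; code[chg == 1] <- 3L
  code[chg == -1] <- 5L; code[chg == -2] <- 6L; code[chg == -3] <- 7L
  code
}

# Write the induced subgraph on `keep` (default: all heavy atoms) as a
# minimal V2000 block. Hydrogens are left implicit; OpenBabel restores
# them from standard valences on read.
.writeV2000 <- function(graph, keep = seq_len(graph$natoms),
                        title = "mol") {
  keep <- sort(keep)
  remap <- integer(graph$natoms)
  remap[keep] <- seq_along(keep)
  b <- graph$bonds
  bkeep <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  chg <- graph$charge[keep]
  lines <- c(title, "  ecfpPool", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(keep), nrow(bkeep)))
  code <- .LEGACY_CHARGE(chg)
  for (k in seq_along(keep)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, graph$elem[keep[k]], code[k]))
  }
  for (r in seq_len(nrow(bkeep))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
      remap[bkeep$a1[r]], remap[bkeep$a2[r]], bkeep$order[r]))
  }
  charged <- which(chg != 0L)
  if (length(charged)) {
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      lines <- c(lines, paste0(sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, chg[grp]), collapse = "")))
    }
  }
  c(lines, "M  END", "$$$$")
}

# Canonical SMILES of an induced heavy-atom subgraph.
.subgraphCanonical <- function(graph, keep) {
  if (!length(keep)) return("")
  txt <- paste0(paste(.writeV2000(graph, keep), collapse = "\n"), "\n")
  out <- .obConvert("SDF", "CAN", txt)
  if (!nzchar(out)) return(NA_character_)
  strsplit(trimws(out), "[\t ]+")[[1]][1]
}
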