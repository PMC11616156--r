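# Fingerprint matrix text formats.

#' Write a fingerprint matrix to text
#'
#' Two lossless plain-text layouts: \code{dense} writes one delimited
#' row per compound with a header of bit indices (plus an \code{id}
#' column); \code{sparse} writes a one-line header \code{"n L"}
#' followed by coordinate triples \code{row column 1} for the set bits.
#'
#' @param m binary integer matrix (rows = compounds).
#' @param path output file.
#' @param format \code{"dense"} or \code{"sparse"}.
#' @return the path, invisibly.
#' @export
writeFingerprints <- function(m, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  if (!is.matrix(m)) stop("fingerprints must be a matrix")
  if (!all(m %in% c(0L, 1L))) stop("fingerprints must be binary")
  if (format == "dense") {
    ids <- rownames(m)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
    df <- data.frame(id = ids, m, check.names = FALSE)
    colnames(df) <- c("id", sprintf("bit%d", seq_len(ncol(m)) - 1L))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
    idx <- which(m == 1L, arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      writeLines(sprintf("%d %d 1", idx[, 1], idx[, 2]), con)
    }
  }
  invisible(path)
}

#' @rdname writeFingerprints
#' @param path input file.
#' @return \code{readFingerprints} returns the binary matrix (dense
#'   format restores rownames).
#' @export
readFingerprints <- function(path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            colClasses = "character")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1]]
    colnames(m) <- NULL
    m
  } else {
    header <- scan(path, what = integer(), nlines = 1, quiet = TRUE)
    trip <- tryCatch(
      utils::read.table(path, skip = 1,
                        col.names = c("row", "col", "val")),
      error = function(e)
        data.frame(row = integer(0), col = integer(0), val = integer(0)))
    m <- matrix(0L, nrow = header[1], ncol = header[2])
    if (nrow(trip)) m[cbind(trip$row, trip$col)] <- 1L
    m
  }
}
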