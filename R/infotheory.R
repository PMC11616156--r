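# Information-theoretic diagnostics: entropy, mutual information,
# chi-squared p-values, and substructure-frequency summaries.

#' Shannon entropy of a binary feature column
#'
#' Plug-in estimate in bits: \eqn{H = -p \log_2 p - (1-p)\log_2(1-p)}
#' with \eqn{p} the empirical mean of the column and \eqn{0 \log 0 = 0}.
#' The entropy of a presence column peaks when the substructure occurs
#' in exactly half of the compounds.
#'
#' @param col binary vector (or a single probability if
#'   \code{prob = TRUE}).
#' @param prob interpret \code{col} as the probability \eqn{p} directly.
#' @return entropy in bits.
#' @examples
#' shannonEntropy(c(0, 1, 0, 1))   # 1 bit
#' shannonEntropy(0.25, prob = TRUE)
#' @export
shannonEntropy <- function(col, prob = FALSE) {
  p <- if (prob) col else {
    if (!length(col)) stop("empty feature column")
    mean(col)
  }
  if (p < 0 || p > 1) stop("probability outside [0, 1]")
  v <- c(p, 1 - p)
  v <- v[v > 0]
  -sum(v * log2(v))
}

#' Empirical mutual information between two binary vectors
#'
#' Plug-in estimate in bits from the empirical 2x2 cell frequencies:
#' \eqn{\hat I = \hat H(X) + \hat H(Y) - \hat H(X, Y)}. Non-negative and
#' symmetric in its arguments.
#'
#' @param col,labels binary vectors of equal length.
#' @return mutual information in bits.
#' @export
mutualInformation <- function(col, labels) {
  if (length(col) != length(labels))
    stop("col and labels must have equal length")
  tab <- c(sum(col == 0 & labels == 0), sum(col == 0 & labels == 1),
           sum(col == 1 & labels == 0), sum(col == 1 & labels == 1))
  .mi2x2(tab)
}

#' Chi-squared independence p-value for a binary feature vs binary label
#'
#' Pearson chi-squared on the 2x2 contingency table, 1 degree of
#' freedom, upper-tail p-value, no continuity correction. A table with a
#' zero margin (constant feature or constant label) carries no signal
#' and returns p = 1.
#'
#' @param col,labels binary vectors of equal length.
#' @return p-value in [0, 1].
#' @export
chiSquaredPValue <- function(col, labels) {
  if (length(col) != length(labels))
    stop("col and labels must have equal length")
  tab <- c(sum(col == 0 & labels == 0), sum(col == 0 & labels == 1),
           sum(col == 1 & labels == 0), sum(col == 1 & labels == 1))
  .chi2pTable(tab)
}

#' Substructure-frequency distribution summary
#'
#' Quantifies the heavy-tailed support-count distribution of a training
#' vocabulary: the percentage of substructures occurring in exactly one
#' compound, in at most 10, in at most 100, and in fewer than half of
#' all compounds (strict inequality), plus the number occurring in more
#' than half and in at least 90 percent of compounds.
#'
#' @param vocab a \code{SubstructureVocabulary}.
#' @return named list with elements \code{mT}, \code{nCompounds},
#'   \code{pctSupport1}, \code{pctSupportLe10}, \code{pctSupportLe100},
#'   \code{pctSupportLtHalf}, \code{nGtHalf}, \code{nGe90pct}.
#' @export
frequencyStats <- function(vocab) {
  stopifnot(is(vocab, "SubstructureVocabulary"))
  cnt <- vocab@counts
  if (!length(cnt)) stop("empty vocabulary")
  m <- length(cnt)
  n <- vocab@nCompounds
  res <- list(
    mT = m,
    nCompounds = n,
    pctSupport1 = 100 * sum(cnt == 1) / m,
    pctSupportLe10 = 100 * sum(cnt <= 10) / m,
    pctSupportLe100 = 100 * sum(cnt <= 100) / m,
    pctSupportLtHalf = 100 * sum(cnt < n / 2) / m,
    nGtHalf = sum(cnt > n / 2),
    nGe90pct = sum(cnt >= 0.9 * n)
  )
  class(res) <- c("frequencySummary", "list")
  res
}

#' @export
print.frequencySummary <- function(x, ...) {
  cat(sprintf(
    paste0("Substructure-frequency summary (m_T = %d over n = %d ",
           "compounds)\n"), x$mT, x$nCompounds))
  cat(sprintf("  support == 1      : %5.1f%%\n", x$pctSupport1))
  cat(sprintf("  support <= 10     : %5.1f%%\n", x$pctSupportLe10))
  cat(sprintf("  support <= 100    : %5.1f%%\n", x$pctSupportLe100))
  cat(sprintf("  support <  n/2    : %5.2f%%\n", x$pctSupportLtHalf))
  cat(sprintf("  support >  n/2    : %d substructures\n", x$nGtHalf))
  cat(sprintf("  support >= 0.9 n  : %d substructures\n", x$nGe90pct))
  invisible(x)
}
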