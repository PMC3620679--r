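#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value for the table \code{rbind(c(a, b),
#' c(c, d))} by summing, over the hypergeometric support fixed by the
#' margins, every table probability not exceeding that of the observed
#' table (up to a relative tolerance of 1e-7 guarding against floating
#' point ties).
#'
#' @param a,b,c,d non-negative cell counts; row 1 is (a, b), row 2 is
#'   (c, d).
#' @return the two-sided p-value.
#' @examples
#' fisherExact2x2(5, 5, 5, 5)    # 1
#' fisherExact2x2(0, 10, 10, 0)  # ~1.08e-5
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (sum(counts) == 0)
    stop("at least one cell must be positive")
  m <- a + b              # row-1 total (white balls)
  n <- c + d              # row-2 total (black balls)
  k <- a + c              # column-1 total (balls drawn)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  # extreme tables can underflow the sum to 0; keep p in (0, 1]
  max(p, .Machine$double.xmin)
}

#' Signed fold enrichment of an observed overlap
#'
#' Under independence the expected overlap between a query of size
#' \code{nQuery} and a target of size \code{nSet} drawn from a background
#' of \code{nBackground} genes is \code{nQuery * nSet / nBackground}.
#' Enrichment is reported as \code{observed/expected}; depletion as the
#' negative reciprocal \code{-expected/observed}, so that e.g. -4.3 reads
#' as 4.3-fold depletion. An observed count of 0 yields \code{fe = NA}
#' (undefined) with the expected count retained.
#'
#' @param observed overlap count.
#' @param nQuery,nSet,nBackground query, target and background sizes.
#' @return a list with components \code{observed}, \code{expected} and
#'   \code{fe}.
#' @examples
#' foldEnrichment(29, 1156, 1974, 18166)$fe  # about -4.33
#' @export
foldEnrichment <- function(observed, nQuery, nSet, nBackground) {
  if (nBackground <= 0) stop("'nBackground' must be positive")
  if (nQuery > nBackground || nSet > nBackground)
    stop("'nQuery' and 'nSet' cannot exceed 'nBackground'")
  if (observed > min(nQuery, nSet))
    stop("'observed' cannot exceed min(nQuery, nSet)")
  expected <- nQuery * nSet / nBackground
  fe <- if (observed == 0) NA_real_
        else if (observed >= expected) observed / expected
        else -expected / observed
  list(observed = observed, expected = expected, fe = fe)
}

#' Gene-set overrepresentation test
#'
#' Builds the 2x2 contingency table of query membership against target
#' membership over the background symbols and returns the observed and
#' expected overlap, the signed fold enrichment and the two-sided Fisher
#' exact p-value. Symbols are uppercased; query or target symbols absent
#' from the background are dropped (with a message giving the count).
#'
#' @param query,target,background character vectors of gene symbols.
#' @param queryName,targetName optional labels carried into the result.
#' @return a one-row data.frame with columns \code{query}, \code{target},
#'   \code{n_query}, \code{n_target}, \code{n_background},
#'   \code{observed}, \code{expected}, \code{fe}, \code{p}.
#' @export
enrichTest <- function(query, target, background,
                       queryName = "query", targetName = "target") {
  bg <- normalizeSymbols(background)
  if (!length(bg)) stop("empty background")
  q <- normalizeSymbols(query)
  t <- normalizeSymbols(target)
  dropped_q <- sum(!(q %in% bg))
  dropped_t <- sum(!(t %in% bg))
  if (dropped_q + dropped_t > 0)
    message(sprintf("enrichTest: dropped %d query and %d target symbols absent from background",
                    dropped_q, dropped_t))
  q <- q[q %in% bg]
  t <- t[t %in% bg]
  if (!length(q))
    stop(sprintf("gene set '%s' is empty after background mapping", queryName))
  if (!length(t))
    stop(sprintf("gene set '%s' is empty after background mapping", targetName))
  a <- sum(q %in% t)
  b <- length(q) - a
  cc <- length(t) - a
  d <- length(bg) - a - b - cc
  fe <- foldEnrichment(a, length(q), length(t), length(bg))
  data.frame(query = queryName, target = targetName,
             n_query = length(q), n_target = length(t),
             n_background = length(bg),
             observed = a, expected = fe$expected, fe = fe$fe,
             p = fisherExact2x2(a, b, cc, d),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control over a batch of tests.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bhFdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
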