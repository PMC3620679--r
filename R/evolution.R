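#' Remove shared genes before rate comparisons
#'
#' Two exclusion rules are used before comparing evolutionary-rate
#' distributions: \code{"pairwise_vs_reference"} removes the intersection
#' of the two sets from both (used when comparing the hotspot-intersected
#' set against housekeeping, tissue-specific or secreted-protein sets, so
#' each set's unique character is compared); \code{"unique_only"} keeps in
#' each set only symbols found in none of the other supplied sets (used
#' for the hot/middle/cold intersected sets, which can share genes).
#'
#' @param sets a named list of character vectors of gene symbols; exactly
#'   two for \code{"pairwise_vs_reference"}, two or more for
#'   \code{"unique_only"}.
#' @param mode exclusion rule.
#' @return a named list of the reduced sets, in input order.
#' @export
excludeCommon <- function(sets,
                          mode = c("pairwise_vs_reference", "unique_only")) {
  mode <- match.arg(mode)
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, normalizeSymbols)
  if (mode == "pairwise_vs_reference") {
    if (length(sets) != 2L)
      stop("'pairwise_vs_reference' expects exactly two sets")
    common <- intersect(sets[[1L]], sets[[2L]])
    out <- lapply(sets, setdiff, y = common)
  } else {
    out <- lapply(seq_along(sets), function(i)
      setdiff(sets[[i]], unique(unlist(sets[-i], use.names = FALSE))))
    names(out) <- names(sets)
  }
  emptied <- names(out)[lengths(out) == 0L & lengths(sets) > 0L]
  if (length(emptied))
    stop(sprintf("exclusion emptied set(s): %s",
                 paste(emptied, collapse = ", ")))
  out
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided Wilcoxon (Mann-Whitney) test. The exact permutation
#' distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y numeric vectors (finite values).
#' @return a list with components \code{statistic} (the rank-sum W for
#'   \code{x}) and \code{p}.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
#' @export
wilcoxonRankSum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y))))
    stop("samples must contain only finite values")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 20L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Compare evolutionary-rate distributions between two gene sets
#'
#' Joins both sets to a per-gene rate table and compares dN, dS and dN/dS
#' with the two-sided Wilcoxon rank-sum test after applying the requested
#' exclusion rule. Missing values are dropped per metric, not listwise.
#' \code{direction} is the sign of \code{median(setB) - median(setA)}, i.e.
#' of the comparison set relative to the reference (first) set, so -1
#' reads "lower than the reference".
#'
#' @param setA reference gene set (character vector of symbols), e.g. the
#'   hotspot-intersected genes.
#' @param setB comparison gene set.
#' @param rates data.frame with columns \code{gene_symbol, dn, ds, dnds}
#'   (as from [readRateTable()]). Duplicate symbols contribute their first
#'   row after sorting.
#' @param exclusionMode \code{"pairwise_vs_reference"} (default),
#'   \code{"unique_only"} handled via [excludeCommon()], or \code{"none"}.
#' @param setNames length-2 character vector of labels for the output.
#' @return a data.frame with one row per metric: \code{metric, n_a, n_b,
#'   direction, p, note} (note is \code{NA} unless the metric could not be
#'   tested).
#' @export
compareRates <- function(setA, setB, rates,
                         exclusionMode = c("pairwise_vs_reference",
                                           "unique_only", "none"),
                         setNames = c("A", "B")) {
  exclusionMode <- match.arg(exclusionMode)
  stopifnot(is.data.frame(rates),
            all(c("gene_symbol", "dn", "ds", "dnds") %in% names(rates)))
  rates <- rates[order(rates$gene_symbol), , drop = FALSE]
  rates <- rates[!duplicated(rates$gene_symbol), , drop = FALSE]
  rownames(rates) <- toupper(rates$gene_symbol)
  if (exclusionMode == "none") {
    pair <- list(normalizeSymbols(setA), normalizeSymbols(setB))
  } else {
    pair <- excludeCommon(stats::setNames(list(setA, setB), setNames),
                          mode = exclusionMode)
  }
  out <- lapply(c("dn", "ds", "dnds"), function(metric) {
    xa <- rates[intersect(pair[[1L]], rownames(rates)), metric]
    xb <- rates[intersect(pair[[2L]], rownames(rates)), metric]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L)
      return(data.frame(metric = metric, n_a = length(xa), n_b = length(xb),
                        direction = NA_integer_, p = NA_real_,
                        note = "insufficient data",
                        stringsAsFactors = FALSE))
    w <- wilcoxonRankSum(xa, xb)
    data.frame(metric = metric, n_a = length(xa), n_b = length(xb),
               direction = sign(stats::median(xb) - stats::median(xa)),
               p = w$p, note = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare two proportions by Fisher's exact test
#'
#' Used for e.g. the fraction of duplicated-gene transcripts among two
#' transcript sets. The 2x2 table is (members, non-members) by group; the
#' fold difference is the signed ratio of the two proportions (group A
#' relative to group B, with depletion as the negative reciprocal).
#'
#' @param aMembers,aTotal member count and total for group A.
#' @param bMembers,bTotal member count and total for group B.
#' @return a one-row data.frame: \code{prop_a, prop_b, fe, p} plus the
#'   input counts.
#' @export
proportionTest <- function(aMembers, aTotal, bMembers, bTotal) {
  if (aTotal <= 0 || bTotal <= 0) stop("group totals must be positive")
  if (aMembers > aTotal || bMembers > bTotal)
    stop("member counts cannot exceed group totals")
  pa <- aMembers / aTotal
  pb <- bMembers / bTotal
  fe <- if (pa == 0 || pb == 0) NA_real_
        else if (pa >= pb) pa / pb else -pb / pa
  data.frame(a_members = aMembers, a_total = aTotal,
             b_members = bMembers, b_total = bTotal,
             prop_a = pa, prop_b = pb, fe = fe,
             p = fisherExact2x2(aMembers, aTotal - aMembers,
                                bMembers, bTotal - bMembers),
             stringsAsFactors = FALSE)
}

#' Enrichment of a gene set across evolutionary-age branches
#'
#' Tests the query set for over- or under-representation in every
#' evolutionary-age branch (0 = oldest through 12 = primate-specific
#' young genes) against the background, with Benjamini-Hochberg control
#' across branches, and reports the fraction of query genes assigned to
#' branch 0.
#'
#' @param query character vector of gene symbols.
#' @param branches named integer vector mapping symbols to branches 0..12
#'   (as from [readBranchAssignment()]); every assigned symbol must be in
#'   the background.
#' @param background character vector of background symbols.
#' @return a list with \code{table} (one row per branch present:
#'   \code{branch, n_branch, observed, expected, fe, p, q}) and
#'   \code{branch0_fraction} (fraction of assigned query genes in branch
#'   0, \code{NA} if none assigned).
#' @export
branchEnrichment <- function(query, branches, background) {
  if (!length(branches)) stop("empty branch assignment")
  if (anyNA(branches) || any(branches < 0L | branches > 12L))
    stop("branch labels must be integers 0..12")
  names(branches) <- toupper(names(branches))
  bg <- normalizeSymbols(background)
  unknown <- setdiff(names(branches), bg)
  if (length(unknown))
    stop(sprintf("%d branch-assigned symbols are not in the background (e.g. %s)",
                 length(unknown), unknown[1L]))
  q <- intersect(normalizeSymbols(query), bg)
  lv <- sort(unique(branches))
  rows <- lapply(lv, function(b) {
    members <- names(branches)[branches == b]
    res <- enrichTest(q, members, bg, queryName = "query",
                      targetName = sprintf("branch%d", b))
    data.frame(branch = b, n_branch = res$n_target,
               observed = res$observed, expected = res$expected,
               fe = res$fe, p = res$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bhFdr(tab$p)
  q_assigned <- q[q %in% names(branches)]
  frac0 <- if (length(q_assigned))
    mean(branches[q_assigned] == 0L) else NA_real_
  list(table = tab, branch0_fraction = frac0)
}
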