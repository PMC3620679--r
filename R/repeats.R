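#' Per-element repeat enrichment between two region sets
#'
#' For each repeat element, builds the 2x2 table of instance counts
#' (instances of the element vs instances of all other elements) by
#' (instance overlaps region set A vs overlaps region set B). An instance
#' overlaps a set when at least one base intersects any of its intervals;
#' instances overlapping both sets are counted in both columns.
#' Significance is controlled across elements by Benjamini-Hochberg, and
#' an element is called significantly overrepresented in A when
#' \code{q < fdr} and \code{fe > 1}. Elements with no instance
#' overlapping either set are skipped (reported in the \code{skipped}
#' attribute); if only one element overlaps at all, there is no
#' comparison margin and every element is skipped.
#'
#' @param repeats a \code{GRanges} of repeat instances with an
#'   \code{element_name} metadata column (as from [readRepeatMasker()]).
#' @param regionsA,regionsB non-empty \code{GRanges} of the two region
#'   sets to compare (e.g. hotspot windows vs the autosomal background).
#' @param fdr significance threshold on q; default 0.05.
#' @return a data.frame with one row per tested element:
#'   \code{element_name, a_count, a_other, b_count, b_other, expected,
#'   fe, p, q, significant}; skipped element names are attached as
#'   \code{attr(, "skipped")}.
#' @export
repeatEnrichment <- function(repeats, regionsA, regionsB, fdr = 0.05) {
  stopifnot(is(repeats, "GRanges"), is(regionsA, "GRanges"),
            is(regionsB, "GRanges"))
  if (!length(regionsA) || !length(regionsB))
    stop("both region sets must be non-empty")
  elem <- mcols(repeats)$element_name
  if (is.null(elem))
    stop("'repeats' needs an 'element_name' metadata column")
  inA <- IRanges::overlapsAny(repeats, regionsA, minoverlap = 1L,
                              ignore.strand = TRUE)
  inB <- IRanges::overlapsAny(repeats, regionsB, minoverlap = 1L,
                              ignore.strand = TRUE)
  elems <- sort(unique(elem))
  aTot <- sum(inA)
  bTot <- sum(inB)
  rows <- list(); skipped <- character(0)
  for (e in elems) {
    sel <- elem == e
    a <- sum(inA & sel)          # element instances overlapping A
    cc <- sum(inB & sel)         # element instances overlapping B
    bOther <- aTot - a           # other-element instances overlapping A
    dOther <- bTot - cc
    if (a + cc == 0L) {
      message(sprintf("repeatEnrichment: element '%s' has no instance overlapping either set; skipped", e))
      skipped <- c(skipped, e)
      next
    }
    if (bOther + dOther == 0L) {
      message(sprintf("repeatEnrichment: no other-element margin for '%s'; skipped", e))
      skipped <- c(skipped, e)
      next
    }
    total <- a + cc + bOther + dOther
    fe <- foldEnrichment(a, a + bOther, a + cc, total)
    rows[[e]] <- data.frame(element_name = e, a_count = a, a_other = bOther,
                            b_count = cc, b_other = dOther,
                            expected = fe$expected, fe = fe$fe,
                            p = fisherExact2x2(a, bOther, cc, dOther),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(element_name = character(0), a_count = integer(0),
                      a_other = integer(0), b_count = integer(0),
                      b_other = integer(0), expected = numeric(0),
                      fe = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bhFdr(out$p)
  out$significant <- out$q < fdr & !is.na(out$fe) & out$fe > 1
  attr(out, "skipped") <- skipped
  out
}

#' Fragile-site / transcript overlap census
#'
#' Counts how many sites overlap at least one transcript by at least one
#' base, and how many transcripts overlap at least one site, reporting
#' both counts and percentages (to one decimal place).
#'
#' @param sites a \code{GRanges} of sites (e.g. fragile sites).
#' @param transcripts a \code{GRanges} of transcript models.
#' @return a list: \code{n_sites, n_sites_hit, pct_sites_hit,
#'   n_transcripts, n_transcripts_hit, pct_transcripts_hit}.
#' @examples
#' s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 150))
#' overlapCensus(s, t)
#' @export
overlapCensus <- function(sites, transcripts) {
  stopifnot(is(sites, "GRanges"), is(transcripts, "GRanges"))
  sHit <- sum(IRanges::overlapsAny(sites, transcripts, minoverlap = 1L,
                                   ignore.strand = TRUE))
  tHit <- sum(IRanges::overlapsAny(transcripts, sites, minoverlap = 1L,
                                   ignore.strand = TRUE))
  list(n_sites = length(sites), n_sites_hit = sHit,
       pct_sites_hit = pct1(sHit, length(sites)),
       n_transcripts = length(transcripts), n_transcripts_hit = tHit,
       pct_transcripts_hit = pct1(tHit, length(transcripts)))
}
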