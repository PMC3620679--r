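.MOTIF_ALPHABET <- c("A", "C", "G", "T", "N")

.checkMotif <- function(motif) {
  motif <- toupper(as.character(motif))
  if (length(motif) != 1L || nchar(motif) < 4L)
    stop("motif must be a single IUPAC string of length >= 4")
  chars <- strsplit(motif, "")[[1L]]
  bad <- setdiff(chars, .MOTIF_ALPHABET)
  if (length(bad))
    stop(sprintf("invalid motif character(s): %s",
                 paste(unique(bad), collapse = ", ")))
  motif
}

.revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# Logical vector over start positions: does the motif match there?
# N in the motif matches any of A/C/G/T; N in the sequence matches nothing.
.matchStarts <- function(chars, motifChars) {
  L <- length(chars)
  m <- length(motifChars)
  if (L < m) return(logical(0))
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    win <- chars[j:(j + L - m)]
    ok <- ok & if (motifChars[j] == "N") win %in% c("A", "C", "G", "T")
               else win == motifChars[j]
  }
  ok
}

#' Count occurrences of a degenerate motif in a sequence
#'
#' Slides the IUPAC motif (alphabet A, C, G, T, N) along the sequence and
#' counts every matching start position; overlapping matches all count.
#' An N in the motif matches any unambiguous base, while an N in the
#' sequence matches nothing (an unknown base is not evidence for a
#' motif). With \code{bothStrands = TRUE} the reverse complement of the
#' motif is also scanned and the union of matching start positions is
#' counted, so a palindromic motif is not double counted.
#'
#' @param seq a DNA sequence: character string, \code{DNAString}, or a
#'   length-1 \code{DNAStringSet}.
#' @param motif IUPAC motif string, e.g. \code{"CCNCCNTNNCCNC"}.
#' @param bothStrands scan the reverse-complement pattern too? Default
#'   \code{TRUE}.
#' @return integer occurrence count.
#' @examples
#' countMotif("CCCCACCCCACCCC", "CCCCACCCC")  # 2 overlapping matches
#' @export
countMotif <- function(seq, motif, bothStrands = TRUE) {
  if (is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- as.character(seq[[1L]])
  } else if (is(seq, "DNAString")) {
    seq <- as.character(seq)
  }
  seq <- toupper(as.character(seq))
  motif <- .checkMotif(motif)
  chars <- strsplit(seq, "")[[1L]]
  hits <- .matchStarts(chars, strsplit(motif, "")[[1L]])
  if (bothStrands) {
    rc <- .revcomp(motif)
    rcHits <- .matchStarts(chars, strsplit(rc, "")[[1L]])
    hits <- hits | rcHits
  }
  sum(hits)
}

.motifPresence <- function(seqs, motif, bothStrands) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  vapply(seqs, function(s) countMotif(s, motif, bothStrands) > 0L,
         logical(1L), USE.NAMES = FALSE)
}

#' Motif-bearing-region enrichment between two region sets
#'
#' The unit of analysis is the region: each region either contains at
#' least one motif occurrence or it does not, and the 2x2 table
#' (motif-bearing vs not) by (set A vs set B) is tested with the
#' two-sided Fisher exact test. The fold difference is the signed ratio
#' of the two motif-bearing proportions (A relative to B).
#'
#' @param regionsA,regionsB character vectors or \code{DNAStringSet}s of
#'   region sequences.
#' @param motif IUPAC motif string.
#' @param bothStrands scan both strands; default \code{TRUE}.
#' @return a one-row data.frame: \code{motif, n_a, with_motif_a, prop_a,
#'   n_b, with_motif_b, prop_b, fe, p}.
#' @export
motifRegionEnrichment <- function(regionsA, regionsB, motif,
                                  bothStrands = TRUE) {
  if (!length(regionsA) || !length(regionsB))
    stop("both region sequence sets must be non-empty")
  motif <- .checkMotif(motif)
  ina <- .motifPresence(regionsA, motif, bothStrands)
  inb <- .motifPresence(regionsB, motif, bothStrands)
  a <- sum(ina); b <- length(ina) - a
  cc <- sum(inb); d <- length(inb) - cc
  pa <- a / length(ina)
  pb <- cc / length(inb)
  fe <- if (pa == 0 || pb == 0) NA_real_
        else if (pa >= pb) pa / pb else -pb / pa
  data.frame(motif = motif, n_a = length(ina), with_motif_a = a,
             prop_a = pa, n_b = length(inb), with_motif_b = cc,
             prop_b = pb, fe = fe, p = fisherExact2x2(a, b, cc, d),
             stringsAsFactors = FALSE)
}
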