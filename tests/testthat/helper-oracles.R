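# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms (full enumeration, per-base
# boolean arrays, regex scans) from the code under test.

# Two-sided Fisher p by full enumeration over the hypergeometric support,
# with probabilities from binomial coefficients.
oracleFisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Per-base boolean-array intersection records on chromosomes <= 100 kb.
# Returns the same columns as intersectSpots().
oracleIntersect <- function(regions, spots, minOverlap = 1L) {
  ids <- recspot:::.regionIds(regions)
  rows <- list()
  for (i in seq_along(regions)) {
    chr <- as.character(GenomicRanges::seqnames(regions))[i]
    rs <- GenomicRanges::start(regions)[i]
    re <- GenomicRanges::end(regions)[i]
    covered <- rep(FALSE, re - rs + 1L)
    nspots <- 0L
    full <- FALSE
    for (j in seq_along(spots)) {
      if (as.character(GenomicRanges::seqnames(spots))[j] != chr) next
      ss <- GenomicRanges::start(spots)[j]
      se <- GenomicRanges::end(spots)[j]
      lo <- max(rs, ss); hi <- min(re, se)
      ov <- max(0L, hi - lo + 1L)
      if (ov >= minOverlap) {
        nspots <- nspots + 1L
        covered[(lo - rs + 1L):(hi - rs + 1L)] <- TRUE
        if (ss >= rs && se <= re) full <- TRUE
      }
    }
    if (nspots > 0L)
      rows[[length(rows) + 1L]] <-
        data.frame(region_id = ids[i], n_spots_overlapped = nspots,
                   covered_bases = sum(covered), contains_full_spot = full,
                   stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(region_id = character(0),
                      n_spots_overlapped = integer(0),
                      covered_bases = integer(0),
                      contains_full_spot = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$region_id), , drop = FALSE]
}

# Per-base occupancy-scan merge of intervals on one chromosome set.
oracleMerge <- function(gr) {
  out <- list()
  for (chr in sort(unique(as.character(GenomicRanges::seqnames(gr))))) {
    sel <- as.character(GenomicRanges::seqnames(gr)) == chr
    st <- GenomicRanges::start(gr)[sel]; en <- GenomicRanges::end(gr)[sel]
    occ <- rep(FALSE, max(en))
    for (i in seq_along(st)) occ[st[i]:en[i]] <- TRUE
    r <- rle(occ)
    pos <- cumsum(c(1L, r$lengths))
    starts <- pos[which(r$values)]
    ends <- starts + r$lengths[r$values] - 1L
    out[[chr]] <- GenomicRanges::GRanges(chr,
                                         IRanges::IRanges(starts, ends))
  }
  suppressWarnings(sort(do.call(c, unname(out)), ignore.strand = TRUE))
}

# Regex-lookahead degenerate motif count; N in the sequence matches
# nothing because the character class excludes it.
oracleMotifCount <- function(seq, motif, bothStrands = TRUE) {
  toRegex <- function(m) gsub("N", "[ACGT]", m, fixed = TRUE)
  starts <- function(m) {
    g <- gregexpr(paste0("(?=", toRegex(m), ")"), seq, perl = TRUE)[[1L]]
    if (g[1L] == -1L) integer(0) else as.integer(g)
  }
  hits <- starts(motif)
  if (bothStrands)
    hits <- union(hits, starts(revcompStr(motif)))
  length(hits)
}

revcompStr <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# Benjamini-Hochberg step-up written out from the definition.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

randomGRanges <- function(n, chroms = c("chr1", "chr2"), maxPos = 1e5,
                          maxLen = 5e3) {
  st <- sample.int(maxPos - maxLen, n, replace = TRUE)
  len <- sample.int(maxLen, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(st, width = len))
}

randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
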