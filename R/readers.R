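#' Read a standardized recombination map
#'
#' Parses a tab-delimited recombination map with columns
#' \code{chrom, start, end, srr} (0-based half-open coordinates, BED
#' convention; lines beginning with \code{#} are treated as comments or
#' headers). Each row is one fixed-width map window carrying its
#' standardized recombination rate.
#'
#' @param path path to the map file.
#' @return a [RecombMap] sorted by (chrom, start).
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t0\t10000\t12.5", f)
#' readRecombMap(f)
#' @export
readRecombMap <- function(path) {
  df <- readTsv(path, col.names = c("chrom", "start", "end", "srr"),
                n_cols = 4L, what = "recombination map")
  if (!nrow(df))
    return(RecombMap(GenomicRanges::GRanges(), srr = numeric(0)))
  start <- asNum(df$start, "start", path)
  end <- asNum(df$end, "end", path)
  srr <- asNum(df$srr, "srr", path)
  if (any(srr < 0))
    stop(sprintf("validation error in %s: negative SRR on data line %d",
                 path, which(srr < 0)[1L]))
  RecombMap(grFromBed0(df$chrom, start, end), srr = srr)
}

#' Write a recombination map
#'
#' Inverse of [readRecombMap()]: writes \code{chrom, start, end, srr} in
#' 0-based half-open coordinates.
#'
#' @param map a [RecombMap].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRecombMap <- function(map, path) {
  stopifnot(is(map, "RecombMap"))
  df <- bed0FromGr(map)
  df$srr <- srr(map)
  writeLines(c("#chrom\tstart\tend\tsrr",
               sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                       format(df$srr, scientific = FALSE, trim = TRUE,
                              digits = 15))),
             path)
  invisible(path)
}

#' Read transcript models
#'
#' Reads BED-like transcript records. Accepted layouts:
#' \itemize{
#'   \item 6-column combined form \code{chrom, start, end, transcript_id,
#'     score, strand, gene_symbol} (7 columns) or \code{chrom, start, end,
#'     transcript_id, score/ignored, gene_symbol} (6 columns where the 6th
#'     field is not a strand character);
#'   \item BED4/BED6 \code{chrom, start, end, transcript_id[, score,
#'     strand]} plus a separate 2-column \code{transcript_id -> gene_symbol}
#'     map given as \code{symbolMap}.
#' }
#' Score and strand are ignored throughout: spot intersection is
#' unstranded.
#'
#' @param path path to the transcript BED file.
#' @param symbolMap optional path to a 2-column TSV mapping transcript_id to
#'   gene_symbol, required when the BED file itself has no symbol column.
#' @return a \code{GRanges} with metadata columns \code{transcript_id} and
#'   \code{gene_symbol}, sorted by (chrom, start).
#' @export
readTranscripts <- function(path, symbolMap = NULL) {
  df <- readTsv(path, what = "transcript annotation")
  if (!nrow(df)) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$transcript_id <- character(0)
    mcols(gr)$gene_symbol <- character(0)
    return(gr)
  }
  if (ncol(df) < 4L)
    stop(sprintf("parse error in %s: need at least 4 columns (chrom, start, end, transcript_id)", path))
  tx <- df[[4L]]
  if (anyDuplicated(tx))
    stop(sprintf("validation error in %s: duplicated transcript_id '%s'",
                 path, tx[duplicated(tx)][1L]))
  sym <- NULL
  if (ncol(df) >= 7L) {
    sym <- df[[7L]]
  } else if (ncol(df) == 6L && !all(df[[6L]] %in% c("+", "-", ".", "*"))) {
    sym <- df[[6L]]
  }
  if (is.null(sym)) {
    if (is.null(symbolMap))
      stop(sprintf("%s has no gene_symbol column and no 'symbolMap' was given", path))
    map <- readTsv(symbolMap, col.names = c("transcript_id", "gene_symbol"),
                   n_cols = 2L, what = "transcript-symbol map")
    idx <- match(tx, map$transcript_id)
    if (anyNA(idx))
      stop(sprintf("transcript '%s' missing from symbol map %s",
                   tx[which(is.na(idx))[1L]], symbolMap))
    sym <- map$gene_symbol[idx]
  }
  if (any(is.na(sym) | !nzchar(sym)))
    stop(sprintf("validation error in %s: empty gene_symbol", path))
  gr <- grFromBed0(df[[1L]], asNum(df[[2L]], "start", path),
                   asNum(df[[3L]], "end", path))
  mcols(gr)$transcript_id <- as.character(tx)
  mcols(gr)$gene_symbol <- toupper(as.character(sym))
  sort(gr, ignore.strand = TRUE)
}

#' Write intervals as BED
#'
#' Writes a \code{GRanges} (or [SpotSet]) as BED3, or BED4 when a name
#' column is available (\code{name} argument, a \code{name}/\code{region_id}
#' metadata column, or the spot label).
#'
#' @param gr intervals to write.
#' @param path output path.
#' @param name optional character vector of interval names (column 4).
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path, name = NULL) {
  df <- bed0FromGr(gr)
  if (is.null(name)) {
    mc <- mcols(gr)
    if ("name" %in% colnames(mc)) name <- mc$name
    else if ("region_id" %in% colnames(mc)) name <- mc$region_id
    else if (is(gr, "SpotSet")) name <- rep(spotLabel(gr), length(gr))
  }
  lines <- if (is.null(name))
    sprintf("%s\t%d\t%d", df$chrom, df$start, df$end)
  else
    sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED interval file
#'
#' @param path BED3+ file (0-based half-open); column 4, when present, is
#'   kept as metadata column \code{name}.
#' @return a sorted \code{GRanges}.
#' @export
readBedIntervals <- function(path) {
  df <- readTsv(path, what = "BED file")
  if (!nrow(df)) return(GenomicRanges::GRanges())
  if (ncol(df) < 3L)
    stop(sprintf("parse error in %s: BED needs at least 3 columns", path))
  gr <- grFromBed0(df[[1L]], asNum(df[[2L]], "start", path),
                   asNum(df[[3L]], "end", path))
  if (ncol(df) >= 4L)
    mcols(gr)$name <- as.character(df[[4L]])
  sort(gr, ignore.strand = TRUE)
}

#' Read gene sets
#'
#' Reads either a one-symbol-per-line file (one unnamed set, named after the
#' file) or a 2-column TSV \code{set_name, symbol} holding several sets.
#' Symbols are uppercased and de-duplicated.
#'
#' @param path gene-set file.
#' @return a named list of character vectors of gene symbols.
#' @export
readGeneSets <- function(path) {
  df <- readTsv(path, what = "gene sets")
  if (!nrow(df))
    return(stats::setNames(list(), character(0)))
  if (ncol(df) == 1L) {
    nm <- sub("\\.[^.]*$", "", basename(path))
    out <- list(normalizeSymbols(df[[1L]]))
    names(out) <- nm
    return(out)
  }
  lapply(split(df[[2L]], factor(df[[1L]], levels = unique(df[[1L]]))),
         normalizeSymbols)
}

#' Read a per-gene evolutionary-rate table
#'
#' Reads a TSV with columns \code{gene_symbol, dn, ds, dnds}; empty fields
#' denote missing values. A supplied \code{dnds} is kept as-is even when it
#' differs from \code{dn/ds} by rounding, since rate tables usually carry
#' precomputed ratios.
#'
#' @param path rate-table file.
#' @return a data.frame with columns \code{gene_symbol, dn, ds, dnds}.
#' @export
readRateTable <- function(path) {
  df <- readTsv(path, col.names = c("gene_symbol", "dn", "ds", "dnds"),
                what = "rate table")
  if (!nrow(df))
    return(data.frame(gene_symbol = character(0), dn = numeric(0),
                      ds = numeric(0), dnds = numeric(0)))
  for (col in c("dn", "ds", "dnds")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]][!nzchar(trimws(ifelse(is.na(df[[col]]), "", df[[col]])))] <- NA
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$gene_symbol <- toupper(df$gene_symbol)
  df[, c("gene_symbol", "dn", "ds", "dnds")]
}

#' Read an evolutionary-age branch assignment
#'
#' @param path TSV with columns \code{gene_symbol, branch} where branch is
#'   an integer 0 (oldest) through 12 (youngest, primate-specific).
#' @return a named integer vector (names are uppercased symbols).
#' @export
readBranchAssignment <- function(path) {
  df <- readTsv(path, col.names = c("gene_symbol", "branch"), n_cols = 2L,
                what = "branch assignment")
  branch <- suppressWarnings(as.integer(df$branch))
  if (nrow(df) && (anyNA(branch) || any(branch < 0L | branch > 12L)))
    stop(sprintf("validation error in %s: branch labels must be integers 0..12", path))
  stats::setNames(branch, toupper(df$gene_symbol))
}

#' Read RepeatMasker-style repeat annotations
#'
#' Reads the UCSC rmsk-like subset \code{chrom, start, end, element_name,
#' family} (0-based half-open).
#'
#' @param path repeat annotation file.
#' @return a sorted \code{GRanges} with metadata columns
#'   \code{element_name} and \code{family}.
#' @export
readRepeatMasker <- function(path) {
  df <- readTsv(path, col.names = c("chrom", "start", "end",
                                    "element_name", "family"),
                what = "repeat annotation")
  if (!nrow(df)) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$element_name <- character(0)
    mcols(gr)$family <- character(0)
    return(gr)
  }
  if (ncol(df) < 4L)
    stop(sprintf("parse error in %s: need chrom, start, end, element_name", path))
  gr <- grFromBed0(df$chrom, asNum(df$start, "start", path),
                   asNum(df$end, "end", path))
  mcols(gr)$element_name <- as.character(df$element_name)
  mcols(gr)$family <- if ("family" %in% names(df))
    as.character(df$family) else NA_character_
  sort(gr, ignore.strand = TRUE)
}

#' Read region sequences from FASTA
#'
#' Sequences are uppercased; the first whitespace-separated token of each
#' header is the region id, and a \code{class=<label>} token, when present,
#' is parsed into the \code{region_class} attribute used by the pipeline's
#' motif stage.
#'
#' @param path FASTA file.
#' @return a \code{DNAStringSet} named by region id, with a
#'   \code{region_class} character vector attached as metadata
#'   (\code{S4Vectors::metadata(x)$region_class}).
#' @export
readRegionSequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[`, "", 1L)
  cls <- rep(NA_character_, length(headers))
  hit <- regmatches(headers, regexpr("class=[^[:space:]]+", headers))
  has <- grepl("class=", headers)
  cls[has] <- sub("^class=", "", hit)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  S4Vectors::metadata(seqs)$region_class <- cls
  seqs
}
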