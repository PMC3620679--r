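# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# stream; seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed))
    return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed)
    old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Deterministic fan-out of one global seed into per-stage child seeds.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 1000003 * k) %% (.Machine$integer.max - 1L))
}

# 0-based half-open (BED) -> GRanges (1-based closed) and back.
grFromBed0 <- function(chrom, start0, end0, ...) {
  start0 <- as.numeric(start0); end0 <- as.numeric(end0)
  bad <- which(!(start0 >= 0 & end0 > start0))
  if (length(bad))
    stop(sprintf("invalid interval on row %d: need 0 <= start < end", bad[1L]))
  GenomicRanges::GRanges(as.character(chrom),
                         IRanges::IRanges(start = start0 + 1, end = end0), ...)
}

bed0FromGr <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Percentage to one decimal, the convention used for census reporting.
pct1 <- function(k, n) {
  if (n == 0) return(0)
  round(100 * k / n, 1)
}

# Uppercased, de-duplicated symbol set.
normalizeSymbols <- function(x, what = "gene set") {
  x <- unique(toupper(as.character(x)))
  x <- x[!is.na(x) & nzchar(x)]
  x
}

readTsv <- function(path, col.names = NULL, n_cols = NULL, what = "file") {
  if (!file.exists(path))
    stop(sprintf("%s not found: %s", what, path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    df <- as.data.frame(matrix(character(0), ncol = length(col.names)))
    names(df) <- col.names
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate whitespace-delimited input
  if (length(fields[[1L]]) == 1L)
    fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (!is.null(n_cols) && any(nf < n_cols))
    stop(sprintf("parse error in %s at line %d: expected %d columns, found %d",
                 what, which(nf < n_cols)[1L], n_cols, nf[which(nf < n_cols)[1L]]))
  ncol_use <- if (is.null(n_cols)) max(nf) else n_cols
  df <- as.data.frame(do.call(rbind, lapply(fields, function(f)
    f[seq_len(ncol_use)])), stringsAsFactors = FALSE)
  if (!is.null(col.names))
    names(df)[seq_along(col.names)] <- col.names
  df
}

asNum <- function(x, what, file = "input") {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("parse error in %s: non-numeric %s on data line %d ('%s')",
                 file, what, bad[1L], x[bad[1L]]))
  out
}
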