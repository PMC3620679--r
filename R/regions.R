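#' Merge transcript models into non-overlapping gene regions
#'
#' Takes the union of transcript intervals per chromosome, ignoring strand.
#' Intervals that merely abut in half-open coordinates (one ends where the
#' next starts) are \emph{not} merged: merging requires at least one shared
#' base. Each output region records the transcript ids that contributed to
#' it.
#'
#' @param transcripts a \code{GRanges} with a \code{transcript_id} metadata
#'   column (as from [readTranscripts()]).
#' @return a sorted \code{GRanges} of pairwise-disjoint regions with
#'   metadata columns \code{region_id} and \code{member_transcripts}
#'   (a \code{CharacterList}).
#' @examples
#' tx <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 6, 21), c(10, 15, 30)))
#' tx$transcript_id <- c("t1", "t2", "t3")
#' mergeTranscripts(tx)  # two regions: [1,15] and [21,30]
#' @export
mergeTranscripts <- function(transcripts) {
  stopifnot(is(transcripts, "GRanges"))
  if (!length(transcripts)) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$region_id <- character(0)
    mcols(gr)$member_transcripts <- IRanges::CharacterList()
    return(gr)
  }
  if (is.null(mcols(transcripts)$transcript_id))
    stop("'transcripts' needs a 'transcript_id' metadata column")
  # min.gapwidth = 0: abutting closed intervals (gap 0 after half-open ->
  # closed conversion) stay separate; >= 1 shared base is required to merge
  regions <- GenomicRanges::reduce(granges(transcripts), min.gapwidth = 0L,
                                   ignore.strand = TRUE)
  regions <- sort(regions, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(regions, transcripts, minoverlap = 1L,
                                    ignore.strand = TRUE)
  members <- unname(IRanges::CharacterList(
    split(mcols(transcripts)$transcript_id[S4Vectors::subjectHits(ov)],
          factor(S4Vectors::queryHits(ov), levels = seq_along(regions)))))
  mcols(regions)$region_id <- sprintf("%s:%d-%d",
                                      as.character(seqnames(regions)),
                                      start(regions) - 1L, end(regions))
  mcols(regions)$member_transcripts <- members
  regions
}

.regionIds <- function(regions) {
  mc <- mcols(regions)
  if ("region_id" %in% colnames(mc)) return(as.character(mc$region_id))
  if ("transcript_id" %in% colnames(mc)) return(as.character(mc$transcript_id))
  sprintf("%s:%d-%d", as.character(seqnames(regions)), start(regions) - 1L,
          end(regions))
}

#' Intersect gene regions with a spot set
#'
#' For every region overlapping at least one spot by \code{minOverlap}
#' bases, reports the number of qualifying spots, the total number of
#' region bases covered by them (the union of region-by-spot
#' intersections, so overlapping spots are not double counted) and whether
#' some spot lies entirely within the region. Strand is ignored.
#'
#' @param regions a \code{GRanges} of gene regions (from
#'   [mergeTranscripts()]) or transcript models.
#' @param spots a [SpotSet] or plain \code{GRanges} of spot intervals.
#' @param minOverlap minimum shared bases for a region/spot pair to count;
#'   default 1.
#' @return a data.frame with one row per intersected region:
#'   \code{region_id}, \code{n_spots_overlapped}, \code{covered_bases},
#'   \code{contains_full_spot}.
#' @export
intersectSpots <- function(regions, spots, minOverlap = 1L) {
  stopifnot(is(regions, "GRanges"), is(spots, "GRanges"))
  minOverlap <- as.integer(minOverlap)
  if (minOverlap < 1L) stop("'minOverlap' must be >= 1")
  ids <- .regionIds(regions)
  empty <- data.frame(region_id = character(0),
                      n_spots_overlapped = integer(0),
                      covered_bases = integer(0),
                      contains_full_spot = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(regions) || !length(spots)) return(empty)
  ov <- GenomicRanges::findOverlaps(regions, spots, minoverlap = minOverlap,
                                    ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  pieces <- GenomicRanges::pintersect(granges(regions)[q], granges(spots)[s])
  hitRegions <- sort(unique(q))
  grp <- factor(q, levels = hitRegions)
  covered <- vapply(split(pieces, grp), function(p)
    sum(GenomicRanges::width(GenomicRanges::reduce(p, ignore.strand = TRUE))),
    integer(1L))
  within <- GenomicRanges::findOverlaps(granges(spots), granges(regions),
                                        type = "within",
                                        ignore.strand = TRUE)
  full <- hitRegions %in% S4Vectors::subjectHits(within)
  data.frame(region_id = ids[hitRegions],
             n_spots_overlapped = as.integer(table(grp)),
             covered_bases = unname(covered),
             contains_full_spot = full,
             stringsAsFactors = FALSE)
}

#' Summarize spot coverage of intersected regions
#'
#' Computes the coverage statistics reported for hotspot-intersected gene
#' regions: the minimum, maximum and median covered bases over the
#' intersected regions, the fraction of intersected regions containing at
#' least one entire spot, and the fraction covered by at least
#' \code{coveredThreshold} bases.
#'
#' @param records intersection records from [intersectSpots()].
#' @param regions the region set the records were derived from (used for
#'   the total-region denominator reported alongside).
#' @param coveredThreshold bases; default 1000.
#' @return a list with components \code{n_regions}, \code{n_intersected},
#'   \code{min_covered}, \code{max_covered}, \code{median_covered},
#'   \code{fraction_full_spot}, \code{fraction_covered_ge_threshold},
#'   \code{covered_threshold}. Statistics are \code{NA} when no region
#'   intersects.
#' @export
coverageSummary <- function(records, regions, coveredThreshold = 1000L) {
  n_regions <- if (is(regions, "GRanges")) length(regions) else nrow(regions)
  if (!nrow(records))
    return(list(n_regions = n_regions, n_intersected = 0L,
                min_covered = NA_real_, max_covered = NA_real_,
                median_covered = NA_real_, fraction_full_spot = NA_real_,
                fraction_covered_ge_threshold = NA_real_,
                covered_threshold = coveredThreshold))
  list(n_regions = n_regions,
       n_intersected = nrow(records),
       min_covered = min(records$covered_bases),
       max_covered = max(records$covered_bases),
       median_covered = stats::median(records$covered_bases),
       fraction_full_spot = mean(records$contains_full_spot),
       fraction_covered_ge_threshold =
         mean(records$covered_bases >= coveredThreshold),
       covered_threshold = coveredThreshold)
}
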