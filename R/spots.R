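#' Classify map windows into hot, middle and cold spots
#'
#' Applies the SRR thresholding rules to a recombination map: hotspots are
#' windows with \code{srr > hotMin} (strict), middle spots satisfy
#' \code{midLo < srr < midHi} (both strict), and cold spots have
#' \code{srr == coldVal}. Windows failing all three rules appear in no set.
#' Each passing window is one spot; contiguous passing windows are not
#' merged.
#'
#' @param map a [RecombMap] (or GRanges with an \code{srr} column).
#' @param hotMin hotspot threshold; default 10 (SRR strictly greater).
#' @param midLo,midHi middle-spot open interval bounds; defaults 0.1 and 1.
#' @param coldVal the cold-spot rate; default 0 (exact equality).
#' @return a named list of three [SpotSet]s: \code{hot}, \code{middle},
#'   \code{cold}.
#' @examples
#' map <- RecombMap(GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 10001, 20001), width = 10000)),
#'   srr = c(12, 0.5, 0))
#' lengths(classifySpots(map))
#' @export
classifySpots <- function(map, hotMin = 10, midLo = 0.1, midHi = 1,
                          coldVal = 0) {
  stopifnot(is(map, "GRanges"))
  if (!(coldVal <= midLo && midLo < midHi && midHi <= hotMin))
    stop("thresholds must satisfy coldVal <= midLo < midHi <= hotMin")
  rate <- srr(map)
  if (length(map) && is.null(rate))
    stop("'map' has no 'srr' metadata column")
  gr <- granges(map)
  mcols(gr)$srr <- rate
  pick <- function(keep, label) SpotSet(gr[which(keep)], label)
  list(hot = pick(rate > hotMin, "hot"),
       middle = pick(rate > midLo & rate < midHi, "middle"),
       cold = pick(rate == coldVal, "cold"))
}

#' Sample spots without replacement
#'
#' Uniform sampling of \code{n} spots, used to draw middle and cold spot
#' sets of the same size as the hotspot set so that downstream gene-set
#' comparisons are balanced.
#'
#' @param spotset a [SpotSet].
#' @param n number of spots to draw; must not exceed the available count.
#' @param seed optional integer seed making the draw reproducible without
#'   touching the caller's RNG stream.
#' @return a sorted [SpotSet] with the same label.
#' @export
sampleSpots <- function(spotset, n, seed = NULL) {
  stopifnot(is(spotset, "SpotSet"))
  n <- as.integer(n)
  if (n < 0L) stop("'n' must be non-negative")
  if (n > length(spotset))
    stop(sprintf("cannot sample %d spots from a set of %d", n,
                 length(spotset)))
  idx <- withSeed(seed, sample.int(length(spotset), n))
  # subsetting a sorted SpotSet by sorted indices preserves class, label
  # and order, so no re-validation pass is needed
  spotset[sort(idx)]
}
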