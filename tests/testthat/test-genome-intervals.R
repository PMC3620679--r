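test_that("recombination map parsing handles simple, empty and bad input", {
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t10000\t12.5", f)
  map <- readRecombMap(f)
  expect_s4_class(map, "RecombMap")
  expect_length(map, 1L)
  expect_equal(srr(map), 12.5)
  expect_equal(GenomicRanges::start(map), 1L)  # 0-based input -> 1-based
  expect_equal(GenomicRanges::end(map), 10000L)

  writeLines("#chrom\tstart\tend\tsrr", f)
  expect_length(readRecombMap(f), 0L)

  writeLines(c("chr1\t0\t10000\t1.0", "chr1\t10000\t20000"), f)
  expect_error(readRecombMap(f), "line 2")
  writeLines("chr1\t0\t10000\t-1", f)
  expect_error(readRecombMap(f), "negative SRR")
})

test_that("a synthetic map round-trips write -> read identically", {
  set.seed(11)
  res <- genRecombMap(simConfig(nChromosomes = 2, chromosomeLength = 5e6,
                                nGenes = 100),
                      hotspotFraction = 0.05, seed = 11)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeRecombMap(res$map, f1)
  back <- readRecombMap(f1)
  writeRecombMap(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(srr(back), srr(res$map))
  expect_identical(GenomicRanges::granges(back),
                   GenomicRanges::granges(res$map))
})

test_that("spot classification applies strict thresholds and partitions", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 1e4, length.out = 6), width = 1e4))
  map <- RecombMap(gr, srr = c(10, 10.01, 0.5, 0, 0.1, 1))
  s <- classifySpots(map)
  expect_equal(length(s$hot), 1L)        # 10 itself is not hot (strict)
  expect_equal(srr(s$hot), 10.01)
  expect_equal(srr(s$middle), 0.5)       # 0.1 and 1 excluded (strict)
  expect_equal(srr(s$cold), 0)
  expect_equal(spotLabel(s$hot), "hot")
  # empty input: three empty sets, not an error
  empty <- classifySpots(RecombMap(GenomicRanges::GRanges(),
                                   srr = numeric(0)))
  expect_true(all(lengths(empty) == 0L))
  expect_error(classifySpots(map, hotMin = 1, midLo = 2, midHi = 3),
               "thresholds")
})

test_that("spot classification matches a per-window brute-force filter", {
  set.seed(42)
  res <- genRecombMap(simConfig(nChromosomes = 2, chromosomeLength = 3e6,
                                nGenes = 50),
                      hotspotFraction = 0.1, seed = 42)
  s <- classifySpots(res$map)
  rate <- srr(res$map)
  expect_equal(length(s$hot), sum(rate > 10))
  expect_equal(length(s$middle), sum(rate > 0.1 & rate < 1))
  expect_equal(length(s$cold), sum(rate == 0))
  # the three rules are mutually exclusive at the default thresholds
  expect_equal(length(s$hot) + length(s$middle) + length(s$cold),
               sum((rate > 10) | (rate > 0.1 & rate < 1) | (rate == 0)))
})

test_that("spot sampling is deterministic, exhaustive at n = |set| and uniform", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 1e4, length.out = 10), width = 1e4))
  ss <- SpotSet(gr, "middle")
  expect_identical(GenomicRanges::granges(sampleSpots(ss, 10, seed = 1)),
                   GenomicRanges::granges(sampleSpots(ss, 10, seed = 99)))
  expect_identical(sampleSpots(ss, 4, seed = 7), sampleSpots(ss, 4, seed = 7))
  expect_error(sampleSpots(ss, 11), "11 spots from a set of 10")
  # uniformity: repeated single draws hit each spot ~1/10 of the time
  set.seed(123)
  draws <- tabulate(vapply(seq_len(10000), function(i)
    GenomicRanges::start(sampleSpots(ss, 1)), numeric(1)) %/% 1e4 + 1L,
    nbins = 10)
  expect_true(all(abs(draws / 10000 - 0.1) <= 0.01))
})

test_that("transcript merging follows half-open conventions and the oracle", {
  tx <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 6, 21), c(10, 15, 30)))  # [0,10),[5,15),[20,30)
  tx$transcript_id <- c("t1", "t2", "t3")
  reg <- mergeTranscripts(tx)
  expect_equal(GenomicRanges::start(reg), c(1L, 21L))
  expect_equal(GenomicRanges::end(reg), c(15L, 30L))
  expect_equal(as.list(reg$member_transcripts),
               list(c("t1", "t2"), "t3"))

  # half-open abutment ([0,10) and [10,20)) is not merged
  ab <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 11), c(10, 20)))
  ab$transcript_id <- c("a", "b")
  expect_length(mergeTranscripts(ab), 2L)

  set.seed(5)
  rnd <- randomGRanges(200)
  rnd$transcript_id <- sprintf("t%03d", seq_len(200))
  merged <- mergeTranscripts(rnd)
  expect_identical(GenomicRanges::granges(merged), oracleMerge(rnd))
  # idempotence: merging the merged regions returns them unchanged
  again <- merged
  again$transcript_id <- again$region_id
  expect_identical(GenomicRanges::granges(mergeTranscripts(again)),
                   GenomicRanges::granges(merged))
})

test_that("region/spot intersection matches the per-base oracle", {
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  reg$transcript_id <- "r1"
  spot <- SpotSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250)),
                  "hot")
  rec <- intersectSpots(reg, spot)
  expect_equal(rec$covered_bases, 50L)
  expect_false(rec$contains_full_spot)
  # [100,200) vs [200,300): zero overlap in half-open coordinates
  spot2 <- SpotSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300)),
                   "hot")
  expect_equal(nrow(intersectSpots(reg, spot2)), 0L)

  set.seed(9)
  regions <- randomGRanges(50)
  regions$transcript_id <- sprintf("r%02d", seq_len(50))
  spots <- SpotSet(unique(randomGRanges(50)), "hot")
  got <- intersectSpots(regions, spots)
  got <- got[order(got$region_id), , drop = FALSE]
  want <- oracleIntersect(regions, spots)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # pair-level symmetry: region overlaps spot iff spot overlaps region
  expect_equal(sort(unique(got$region_id)),
               sort(unique(recspot:::.regionIds(regions)[
                 S4Vectors::subjectHits(GenomicRanges::findOverlaps(
                   spots, regions, ignore.strand = TRUE))])))
  # covered bases never exceed region length, invariant under spot order
  lens <- GenomicRanges::width(regions)[
    match(got$region_id, recspot:::.regionIds(regions))]
  expect_true(all(got$covered_bases <= lens))
  shuf <- intersectSpots(regions, SpotSet(sample(
    GenomicRanges::granges(spots)), "hot"))
  expect_equal(shuf[order(shuf$region_id), ], got,
               ignore_attr = "row.names")
})

test_that("minimum-overlap filtering is honoured", {
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  reg$transcript_id <- "r"
  spot <- SpotSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(991, 2000)),
                  "hot")
  expect_equal(intersectSpots(reg, spot, minOverlap = 10)$covered_bases, 10L)
  expect_equal(nrow(intersectSpots(reg, spot, minOverlap = 11)), 0L)
  expect_error(intersectSpots(reg, spot, minOverlap = 0), "minOverlap")
})

test_that("coverage summaries report fractions and medians as planted", {
  # planted geometry: 7 of 10 regions fully contain a spot
  reg <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 2e4, length.out = 10), width = 1.5e4))
  reg$transcript_id <- sprintf("r%d", 1:10)
  inside <- GenomicRanges::shift(GenomicRanges::resize(reg[1:7], 5e3,
                                                       fix = "start"), 100)
  straddle <- GenomicRanges::shift(reg[8:10], 1e4)  # partial overlap
  spots <- SpotSet(c(inside, straddle), "hot")
  recs <- intersectSpots(reg, spots)
  cov <- coverageSummary(recs, reg)
  expect_equal(cov$fraction_full_spot, 0.7)
  expect_equal(cov$n_intersected, 10L)
  one <- data.frame(region_id = "x", n_spots_overlapped = 1L,
                    covered_bases = 10000L, contains_full_spot = TRUE)
  expect_equal(coverageSummary(one, reg[1])$median_covered, 10000L)
  expect_equal(coverageSummary(one, reg[1])$fraction_full_spot, 1.0)
  empty <- intersectSpots(reg[0], spots)
  expect_true(is.na(coverageSummary(empty, reg)$median_covered))
})
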