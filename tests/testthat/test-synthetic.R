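smallConfig <- function(...) {
  simConfig(nChromosomes = 2, chromosomeLength = 5e6, nGenes = 150,
            geneMeanLength = 1e4, ...)
}

test_that("synthetic maps honour the hotspot fraction and determinism", {
  cfg <- smallConfig()
  none <- genRecombMap(cfg, hotspotFraction = 0, seed = 1)
  expect_true(all(srr(none$map) <= 10))
  expect_length(classifySpots(none$map)$hot, 0L)

  big <- genRecombMap(simConfig(nChromosomes = 2, chromosomeLength = 5e7,
                                nGenes = 100),
                      hotspotFraction = 0.05, seed = 2)
  expect_equal(length(big$map), 10000L)
  nHot <- length(classifySpots(big$map)$hot)
  expect_true(abs(nHot - 500) <= 50)  # binomial band around 0.05 * 10,000
  expect_equal(nHot, big$truth$n_hot_windows)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeRecombMap(genRecombMap(cfg, 0.05, seed = 7)$map, f1)
  writeRecombMap(genRecombMap(cfg, 0.05, seed = 7)$map, f2)
  expect_identical(readLines(f1), readLines(f2))
  # window tiling: fixed width except possibly the last per chromosome
  m <- genRecombMap(simConfig(nChromosomes = 1, chromosomeLength = 2.5e4,
                              nGenes = 1, geneMeanLength = 1e3), 0.1,
                    seed = 1)$map
  expect_equal(GenomicRanges::width(m), c(1e4, 1e4, 5e3))
})

test_that("gene placement follows the hotspot bias", {
  cfg <- simConfig(nChromosomes = 2, chromosomeLength = 1e7, nGenes = 2000,
                   geneMeanLength = 300, geneLengthSdlog = 0.1,
                   maxTranscripts = 1)
  map <- genRecombMap(cfg, hotspotFraction = 0.1, seed = 5)$map
  hot <- classifySpots(map)$hot

  # bias 0: no gene may touch a hot window
  tx0 <- genGeneAnnotation(cfg, map, hotspotBias = 0, seed = 6)
  expect_equal(sum(IRanges::overlapsAny(tx0, hot)), 0L)

  # bias 1 with genes much shorter than windows: the fraction of genes in
  # hot windows tracks the hot base fraction within 3 standard errors
  tx1 <- genGeneAnnotation(cfg, map, hotspotBias = 1, seed = 7)
  hotFrac <- sum(GenomicRanges::width(hot)) / (2 * 1e7)
  got <- mean(IRanges::overlapsAny(tx1, hot))
  se <- sqrt(hotFrac * (1 - hotFrac) / 2000)
  expect_lt(abs(got - hotFrac), 3 * se + 300 / 1e4 * hotFrac)

  # strong bias pushes far more genes into hot windows
  tx5 <- genGeneAnnotation(cfg, map, hotspotBias = 10, seed = 8)
  expect_gt(mean(IRanges::overlapsAny(tx5, hot)), 2 * got)
})

test_that("overlapping transcripts of one gene merge back to one region", {
  cfg <- smallConfig()
  map <- genRecombMap(cfg, 0.05, seed = 3)$map
  tx <- genGeneAnnotation(cfg, map, seed = 4)
  reg <- mergeTranscripts(tx)
  perGene <- split(tx$transcript_id, tx$gene_symbol)
  # every transcript of a gene lands in the same merged region
  memb <- rep(seq_along(reg), lengths(reg$member_transcripts))
  names(memb) <- unlist(reg$member_transcripts)
  sameRegion <- vapply(perGene, function(ids)
    length(unique(memb[ids])) == 1L, logical(1))
  expect_true(all(sameRegion))
})

test_that("planted gene-set enrichments are feasible, calibrated and saturable", {
  bg <- sprintf("G%04d", 1:2000)
  hi <- sample(bg, 300)
  # f = 1: realized overlap inside the central 95% binomial band around
  # independence in >= 90% of seeds
  p0 <- 200 / 2000
  lo <- qbinom(0.025, 300, p0); hihi <- qbinom(0.975, 300, p0)
  inside <- 0L
  for (s in 1:100) {
    gs <- genGeneSets(bg, hi, plantedFe = c(S = 1), setSizes = c(S = 200),
                      seed = s)
    ov <- gs$truth$realized$overlap_hi
    if (ov >= lo && ov <= hihi) inside <- inside + 1L
  }
  expect_gte(inside, 90L)

  # saturation: a huge planted fe drives the whole set into the HI genes
  sat <- genGeneSets(bg, hi, plantedFe = c(S = 500), setSizes = c(S = 30),
                     seed = 1)
  expect_true(all(sat$sets$S %in% toupper(hi)))
  expect_error(genGeneSets(bg, hi, plantedFe = c(S = 50),
                           setSizes = c(S = 1500), seed = 1),
               "infeasible")
  expect_error(genGeneSets(bg, hi, plantedFe = c(S = -1),
                           setSizes = c(S = 10), seed = 1), "> 0")
})

test_that("planted rate shifts behave as documented", {
  bg <- sprintf("G%04d", 1:800)
  # ds can be drawn exactly 0, in which case dnds is absent
  r <- genRateTable(bg, dsZeroProb = 0.2, seed = 9)
  expect_gt(sum(r$ds == 0), 0)
  expect_true(all(is.na(r$dnds[r$ds == 0])))
  expect_true(all(abs(r$dnds[r$ds > 0] - r$dn[r$ds > 0] / r$ds[r$ds > 0])
                  < 1e-12))

  # with no shifts the comparison p-values are uniform across seeds
  pvals <- vapply(1:60, function(s) {
    rt <- genRateTable(bg, seed = 100 + s)
    a <- sample(bg, 150); b <- sample(setdiff(bg, a), 150)
    cmp <- compareRates(a, b, rt, exclusionMode = "none")
    cmp$p[cmp$metric == "dn"]
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)

  # priority order: the first shifted set wins for shared genes
  sets <- list(S1 = bg[1:100], S2 = bg[50:150])
  shifted <- genRateTable(bg, sets = sets,
                          rateShifts = c(S1 = 0.5, S2 = -0.5), seed = 11)
  base <- genRateTable(bg, seed = 11)
  expect_equal(shifted$dn[1:100], pmax(base$dn[1:100] + 0.5, 0))
  expect_equal(shifted$dn[101:150],
               pmax(base$dn[101:150] - 0.5, 0))  # S1 claims the overlap
  expect_equal(shifted$dn[151:800], base$dn[151:800])
})

test_that("sequence generation plants motif presence per class", {
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 1000, length.out = 60), width = 400))
  regions$region_id <- sprintf("r%d", 1:60)
  regions$region_class <- rep(c("A", "B"), each = 30)

  # rate 1 vs 0 for a long motif in short regions, where a chance match
  # of the forward 9-mer is vanishingly rare: planting is the only
  # realistic source of matches
  gen <- genSequencesAndRepeats(regions,
                                motifRates = list(A = c(CCCCACCCC = 1),
                                                  B = c(CCCCACCCC = 0)),
                                seqLength = 150, seed = 21)
  hasA <- vapply(as.character(gen$sequences[1:30]),
                 function(s) countMotif(s, "CCCCACCCC",
                                        bothStrands = FALSE) > 0,
                 logical(1))
  hasB <- vapply(as.character(gen$sequences[31:60]),
                 function(s) countMotif(s, "CCCCACCCC",
                                        bothStrands = FALSE) > 0,
                 logical(1))
  expect_true(all(hasA))
  expect_false(any(hasB))

  # rate 0 everywhere: the enrichment test stays null in >= 90% of seeds
  nullSig <- 0L
  for (s in 1:40) {
    g <- genSequencesAndRepeats(regions,
                                motifRates = list(A = c(CCCCACCCC = 0),
                                                  B = c(CCCCACCCC = 0)),
                                seqLength = 300, seed = 200 + s)
    res <- motifRegionEnrichment(g$sequences[1:30], g$sequences[31:60],
                                 "CCCCACCCC")
    if (res$p < 0.05) nullSig <- nullSig + 1L
  }
  expect_lte(nullSig, 4L)
})

test_that("a written bundle round-trips through the package readers", {
  cfg <- smallConfig()
  b <- simulateBundle(cfg, seed = 33,
                      setSizes = c(HK = 20, TiGER = 40, SPD = 20,
                                   DGD = 40, OMIM = 25, MD = 15, CGC = 8,
                                   TICdb = 6, dbCRID = 8, InteCR = 10),
                      nBackgroundSeqRegions = 40)
  dir <- withr::local_tempdir()
  writeSimBundle(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("map.tsv", "genes.bed", "sets.tsv", "rates.tsv", "branches.tsv",
      "regions.fa", "rmsk.tsv", "fragile.bed", "truth.json")))))
  map <- readRecombMap(file.path(dir, "map.tsv"))
  expect_equal(srr(map), srr(b$map))
  tx <- readTranscripts(file.path(dir, "genes.bed"))
  expect_equal(length(tx), length(b$transcripts))
  expect_setequal(tx$transcript_id, b$transcripts$transcript_id)
  sets <- readGeneSets(file.path(dir, "sets.tsv"))
  expect_equal(lapply(sets, sort), lapply(b$sets[names(sets)], sort))
  rates <- readRateTable(file.path(dir, "rates.tsv"))
  expect_equal(rates$dn, b$rates$dn, tolerance = 1e-9)
  expect_equal(sum(is.na(rates$dnds)), sum(is.na(b$rates$dnds)))
  seqs <- readRegionSequences(file.path(dir, "regions.fa"))
  expect_identical(as.character(seqs), as.character(b$sequences),
                   ignore_attr = TRUE)
  expect_equal(S4Vectors::metadata(seqs)$region_class,
               S4Vectors::metadata(b$sequences)$region_class)
  rm <- readRepeatMasker(file.path(dir, "rmsk.tsv"))
  expect_equal(length(rm), length(b$repeats))
  expect_equal(table(rm$element_name), table(b$repeats$element_name))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$version, "1")
  expect_equal(truth$seed, 33)

  # same config and seed give a byte-identical bundle
  dir2 <- withr::local_tempdir()
  b2 <- simulateBundle(cfg, seed = 33,
                       setSizes = c(HK = 20, TiGER = 40, SPD = 20,
                                    DGD = 40, OMIM = 25, MD = 15, CGC = 8,
                                    TICdb = 6, dbCRID = 8, InteCR = 10),
                       nBackgroundSeqRegions = 40)
  writeSimBundle(b2, dir2)
  for (f in list.files(dir))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
})
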