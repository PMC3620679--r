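.PLANTED_FE <- c(HK = 0.23, TiGER = 1.3, SPD = 1.4, DGD = 1.0,
                 OMIM = 1.3, MD = 1.5, CGC = 2.0, TICdb = 2.5,
                 dbCRID = 2.9, InteCR = 2.4)
.SET_SIZES <- c(HK = 197, TiGER = 471, SPD = 167, DGD = 439,
                OMIM = 262, MD = 163, CGC = 42, TICdb = 24,
                dbCRID = 40, InteCR = 61)
.RATE_SHIFTS <- c(TiGER = 0.015, SPD = 0.015, HK = -0.02, HI = 0.01)
.REPEAT_RATIOS <- c(THE1B = 2, THE1A = 2, "CT-rich" = 1.5, L2 = 1.5,
                    MIRb = 1.5, AluY = 1, L1M = 1, MIR = 1, MLT1A = 1,
                    LTR7 = 1)

.defaultMotifRates <- function(hi = 0.35, bg = 0.15) {
  list(HI = stats::setNames(rep(hi, 3), .DEFAULT_MOTIFS),
       background = stats::setNames(rep(bg, 3), .DEFAULT_MOTIFS))
}

#' Simulate a complete analysis input bundle
#'
#' Generates every input the pipeline consumes on one synthetic genome:
#' recombination map, transcript models, gene sets with planted fold
#' enrichments, a rate table with planted shifts, an evolutionary-age
#' branch assignment, region sequences with planted motif rates, repeat
#' annotations with planted density ratios, and fragile sites. The
#' generating parameters (the ground truth) are recorded in
#' \code{$truth} for recovery tests.
#'
#' With \code{effects = "planted"} (default) the planted magnitudes
#' mirror those reported for human hotspot analyses (housekeeping depletion near
#' 4.3-fold, disease-set enrichments between 1.3 and 2.9, faster
#' evolutionary rates for tissue-specific and secreted-protein sets,
#' elevated hotspot-motif rates in HI regions, and known
#' hotspot-enriched repeat families at elevated density). With
#' \code{effects = "null"} every planted effect is neutral, for
#' calibration runs. Individual parameters can be overridden.
#'
#' One global \code{seed} fans out into fixed per-stage child seeds, so
#' each stage is independently reproducible and the whole bundle is a
#' pure function of (config, parameters, seed).
#'
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @param effects \code{"planted"} or \code{"null"}.
#' @param hotspotFraction,coldMass see [genRecombMap()].
#' @param hotspotBias see [genGeneAnnotation()].
#' @param plantedFe,setSizes see [genGeneSets()].
#' @param rateShifts see [genRateTable()].
#' @param branch0Background,branch0Hi see [genBranchAssignment()].
#' @param motifRates,repeatDensityRatio,seqLength,baseIntensity see
#'   [genSequencesAndRepeats()].
#' @param nBackgroundSeqRegions number of background gene regions given
#'   sequences for the motif stage; default 300.
#' @param nFragileSites,siteLength see [genFragileSites()].
#' @param outDir optional directory; when given, the bundle is also
#'   written to disk via [writeSimBundle()].
#' @return a list of class \code{recspotBundle} with components
#'   \code{config, seed, map, transcripts, sets, rates, branches,
#'   sequences, repeats, fragileSites, truth}.
#' @export
simulateBundle <- function(config = simConfig(), seed = 1L,
                           effects = c("planted", "null"),
                           hotspotFraction = 0.05, coldMass = 0.3,
                           hotspotBias = 1,
                           plantedFe = .PLANTED_FE, setSizes = .SET_SIZES,
                           rateShifts = .RATE_SHIFTS,
                           branch0Background = 0.55, branch0Hi = 0.8,
                           motifRates = .defaultMotifRates(),
                           repeatDensityRatio = .REPEAT_RATIOS,
                           seqLength = 1000L, baseIntensity = 5e-5,
                           nBackgroundSeqRegions = 300L,
                           nFragileSites = 12L, siteLength = 5e5,
                           outDir = NULL) {
  effects <- match.arg(effects)
  if (effects == "null") {
    plantedFe[] <- 1
    rateShifts[] <- 0
    branch0Hi <- branch0Background
    motifRates <- .defaultMotifRates(0.15, 0.15)
    repeatDensityRatio[] <- 1
  }
  mapRes <- genRecombMap(config, hotspotFraction, coldMass,
                         seed = childSeed(seed, 1))
  tx <- genGeneAnnotation(config, mapRes$map, hotspotBias,
                          seed = childSeed(seed, 2))
  spots <- classifySpots(mapRes$map)
  hiSymbols <- sort(unique(mcols(tx)$gene_symbol[
    IRanges::overlapsAny(tx, spots$hot, minoverlap = 1L,
                         ignore.strand = TRUE)]))
  background <- sort(unique(mcols(tx)$gene_symbol))
  gs <- genGeneSets(background, hiSymbols, plantedFe, setSizes,
                    seed = childSeed(seed, 3))
  rates <- genRateTable(background,
                        sets = c(gs$sets, list(HI = hiSymbols)),
                        rateShifts = rateShifts,
                        seed = childSeed(seed, 4))
  branches <- genBranchAssignment(background, hiSymbols,
                                  branch0Background, branch0Hi,
                                  seed = childSeed(seed, 5))
  # sequence regions: merged HI gene regions vs a background sample of
  # merged gene regions (the background may include HI regions, as the
  # full-annotation background does)
  hiTx <- tx[mcols(tx)$gene_symbol %in% hiSymbols]
  hiRegions <- mergeTranscripts(hiTx)
  allRegions <- mergeTranscripts(tx)
  nbg <- min(nBackgroundSeqRegions, length(allRegions))
  bgIdx <- withSeed(childSeed(seed, 6),
                    sort(sample.int(length(allRegions), nbg)))
  seqRegions <- c(granges(hiRegions), granges(allRegions)[bgIdx])
  mcols(seqRegions)$region_id <- c(
    paste0("HI_", mcols(hiRegions)$region_id),
    paste0("BG_", mcols(allRegions)$region_id[bgIdx]))
  mcols(seqRegions)$region_class <- c(rep("HI", length(hiRegions)),
                                      rep("background", nbg))
  seqRes <- genSequencesAndRepeats(seqRegions, motifRates = motifRates,
                                   repeatDensityRatio = NULL,
                                   seqLength = seqLength,
                                   seed = childSeed(seed, 7))
  # repeat regions: hot spots vs the autosomal complement
  extent <- GenomicRanges::GRanges(
    .chromNames(config),
    IRanges::IRanges(1, config$chromosomeLength))
  complement <- GenomicRanges::setdiff(extent, granges(spots$hot),
                                       ignore.strand = TRUE)
  repRegions <- c(granges(spots$hot), complement)
  mcols(repRegions)$region_id <- sprintf("r%d", seq_along(repRegions))
  mcols(repRegions)$region_class <- c(rep("hot", length(spots$hot)),
                                      rep("background",
                                          length(complement)))
  repRes <- genSequencesAndRepeats(repRegions, motifRates = NULL,
                                   repeatDensityRatio = repeatDensityRatio,
                                   classA = "hot", classB = "background",
                                   baseIntensity = baseIntensity,
                                   seed = childSeed(seed, 8))
  fragile <- genFragileSites(config, nFragileSites, siteLength,
                             seed = childSeed(seed, 9))
  truth <- list(version = "1", seed = seed, effects = effects,
                map = mapRes$truth,
                hotspot_bias = hotspotBias,
                n_hi_genes = length(hiSymbols),
                gene_sets = gs$truth,
                rate_shifts = as.list(rateShifts),
                branch0_background = branch0Background,
                branch0_hi = branch0Hi,
                motif_rates = motifRates,
                repeat_density_ratio = as.list(repeatDensityRatio))
  bundle <- structure(list(config = config, seed = seed,
                           map = mapRes$map, transcripts = tx,
                           sets = gs$sets, rates = rates,
                           branches = branches,
                           sequences = seqRes$sequences,
                           repeats = repRes$repeats,
                           fragileSites = fragile, truth = truth),
                      class = "recspotBundle")
  if (!is.null(outDir))
    writeSimBundle(bundle, outDir)
  bundle
}

#' @export
print.recspotBundle <- function(x, ...) {
  cat("recspot synthetic bundle\n")
  cat(sprintf("  seed %s, effects '%s'\n", x$seed, x$truth$effects))
  cat(sprintf("  %d map windows, %d transcripts, %d gene sets, %d repeat instances\n",
              length(x$map), length(x$transcripts), length(x$sets),
              length(x$repeats)))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Writes \code{map.tsv}, \code{genes.bed} (6-column combined form with
#' the gene symbol in column 6), \code{sets.tsv}, \code{rates.tsv},
#' \code{branches.tsv}, \code{regions.fa} (headers carry
#' \code{class=...}), \code{rmsk.tsv}, \code{fragile.bed} and
#' \code{truth.json} (schema version in its \code{version} field). The
#' files round-trip through the package readers.
#'
#' @param bundle a \code{recspotBundle}.
#' @param outDir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSimBundle <- function(bundle, outDir) {
  stopifnot(inherits(bundle, "recspotBundle"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outDir, f)
  writeRecombMap(bundle$map, fp("map.tsv"))
  txd <- bed0FromGr(bundle$transcripts)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", txd$chrom, txd$start, txd$end,
                     mcols(bundle$transcripts)$transcript_id,
                     mcols(bundle$transcripts)$gene_symbol),
             fp("genes.bed"))
  setLines <- unlist(lapply(names(bundle$sets), function(nm)
    sprintf("%s\t%s", nm, bundle$sets[[nm]])), use.names = FALSE)
  writeLines(setLines, fp("sets.tsv"))
  r <- bundle$rates
  fmt <- function(v) ifelse(is.na(v), "",
                            format(v, scientific = FALSE, trim = TRUE,
                                   digits = 10))
  writeLines(sprintf("%s\t%s\t%s\t%s", r$gene_symbol, fmt(r$dn), fmt(r$ds),
                     fmt(r$dnds)), fp("rates.tsv"))
  writeLines(sprintf("%s\t%d", names(bundle$branches), bundle$branches),
             fp("branches.tsv"))
  if (!is.null(bundle$sequences)) {
    cls <- S4Vectors::metadata(bundle$sequences)$region_class
    writeLines(as.vector(rbind(
      sprintf(">%s class=%s", names(bundle$sequences), cls),
      as.character(bundle$sequences))), fp("regions.fa"))
  }
  if (!is.null(bundle$repeats)) {
    rd <- bed0FromGr(bundle$repeats)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s", rd$chrom, rd$start, rd$end,
                       mcols(bundle$repeats)$element_name,
                       mcols(bundle$repeats)$family), fp("rmsk.tsv"))
  }
  writeBed(bundle$fragileSites, fp("fragile.bed"))
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", null = "null")
  invisible(outDir)
}
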