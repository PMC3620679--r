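#' Build a pipeline run configuration
#'
#' Collects input locations (or in-memory objects) and analysis
#' parameters for [runPipeline()]. Inputs may be file paths (read with
#' the package readers) or the corresponding objects; a
#' \code{recspotBundle} from [simulateBundle()] can be passed directly
#' to [runPipeline()] instead.
#'
#' @param map recombination map: path or [RecombMap]. Required.
#' @param genes transcript models: path or \code{GRanges}. Required.
#' @param symbolMap optional transcript-to-symbol map path (see
#'   [readTranscripts()]).
#' @param sets gene sets: path or named list of symbol vectors.
#' @param rates rate table: path or data.frame.
#' @param branches branch assignment: path or named integer vector.
#' @param sequences region sequences: FASTA path or \code{DNAStringSet}
#'   with a \code{region_class} metadata entry.
#' @param repeats repeat annotation: path or \code{GRanges}.
#' @param fragileSites fragile sites: path or \code{GRanges}.
#' @param hotMin,midLo,midHi,coldVal spot thresholds (see
#'   [classifySpots()]).
#' @param minOverlap intersection minimum; default 1 base.
#' @param sampleN middle/cold sample size; default the hotspot count.
#' @param fdr batch false discovery rate; default 0.05.
#' @param coveredThreshold coverage-summary threshold; default 1000.
#' @param motifs hotspot motifs scanned; default the three canonical
#'   hotspot motifs.
#' @param rateCompareSets sets compared against the HI set with the
#'   pairwise exclusion rule; default \code{c("HK", "TiGER", "SPD")}
#'   (those present).
#' @param seed integer seed for the middle/cold sampling.
#' @return a list of class \code{recspotConfig}.
#' @export
runConfig <- function(map, genes, symbolMap = NULL, sets = NULL,
                      rates = NULL, branches = NULL, sequences = NULL,
                      repeats = NULL, fragileSites = NULL,
                      hotMin = 10, midLo = 0.1, midHi = 1, coldVal = 0,
                      minOverlap = 1L, sampleN = NULL, fdr = 0.05,
                      coveredThreshold = 1000L,
                      motifs = .DEFAULT_MOTIFS,
                      rateCompareSets = c("HK", "TiGER", "SPD"),
                      seed = 1L) {
  if (!(coldVal <= midLo && midLo < midHi && midHi <= hotMin))
    stop("thresholds must satisfy coldVal <= midLo < midHi <= hotMin")
  cfg <- list(map = map, genes = genes, symbolMap = symbolMap,
              sets = sets, rates = rates, branches = branches,
              sequences = sequences, repeats = repeats,
              fragileSites = fragileSites,
              hotMin = hotMin, midLo = midLo, midHi = midHi,
              coldVal = coldVal, minOverlap = as.integer(minOverlap),
              sampleN = sampleN, fdr = fdr,
              coveredThreshold = coveredThreshold, motifs = motifs,
              rateCompareSets = rateCompareSets, seed = seed)
  class(cfg) <- "recspotConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys are the arguments of [runConfig()], with input values
#' given as file paths. Keys in \code{overrides} replace file values.
#'
#' @param path YAML file.
#' @param overrides named list of overriding values.
#' @return a \code{recspotConfig}.
#' @export
readRunConfig <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(runConfig, vals)
}

.resolve <- function(x, reader, ...) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

.bundleConfig <- function(bundle, ...) {
  runConfig(map = bundle$map, genes = bundle$transcripts,
            sets = bundle$sets, rates = bundle$rates,
            branches = bundle$branches, sequences = bundle$sequences,
            repeats = bundle$repeats, fragileSites = bundle$fragileSites,
            seed = bundle$seed, ...)
}

#' Run the full hotspot-intersected-gene analysis
#'
#' Executes the pipeline stages in order: spot classification; sampling
#' of middle and cold spots to the hotspot count; transcript-by-spot
#' intersection yielding the HI, MI and CI gene sets; hotspot coverage
#' summary over merged HI gene regions; gene-set enrichment of every
#' supplied set in the HI genes; evolutionary-rate comparisons (HI vs
#' HK/TiGER/SPD with pairwise common-gene exclusion, HI vs MI and CI on
#' unique genes only); duplicated-gene proportion comparison of HI vs HK
#' transcripts; evolutionary-age branch enrichment; hotspot-motif
#' region enrichment (HI vs background region sequences); repeat-element
#' enrichment (hot windows vs the autosomal complement); and the
#' fragile-site census. Optional stages with missing inputs are skipped
#' with a log entry; failures in optional stages are logged and the run
#' continues.
#'
#' Batch tables (gene-set panel, branches, motifs, repeat elements)
#' carry a within-table Benjamini-Hochberg \code{q} column; the
#' run-level \code{findings} table pools all batch hypotheses under one
#' BH adjustment at the configured FDR. Planned pairwise comparisons
#' (rate comparisons, the duplicated-gene proportion) are reported with
#' raw p-values and are not part of \code{findings}.
#'
#' @param config a \code{recspotConfig} from [runConfig()] /
#'   [readRunConfig()], a YAML path, or a \code{recspotBundle}.
#' @return a list of class \code{recspotReport}; see [writeReport()].
#' @export
runPipeline <- function(config) {
  if (inherits(config, "recspotBundle"))
    config <- .bundleConfig(config)
  if (is.character(config))
    config <- readRunConfig(config)
  stopifnot(inherits(config, "recspotConfig"))
  log <- character(0)
  skipped <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  skip <- function(stage, why) {
    skipped <<- c(skipped, stage)
    note("stage %s skipped: %s", stage, why)
  }
  runOptional <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      skip(stage, conditionMessage(e))
      NULL
    })
  }

  map <- .resolve(config$map, readRecombMap)
  if (is.null(map)) stop("stage read_map: recombination map is required")
  tx <- if (is.character(config$genes))
    readTranscripts(config$genes, config$symbolMap) else config$genes
  if (is.null(tx)) stop("stage read_genes: gene models are required")
  note("read %d map windows and %d transcripts (%d gene symbols)",
       length(map), length(tx), length(unique(mcols(tx)$gene_symbol)))
  sets <- .resolve(config$sets, readGeneSets)
  rates <- .resolve(config$rates, readRateTable)
  branches <- .resolve(config$branches, readBranchAssignment)
  sequences <- .resolve(config$sequences, readRegionSequences)
  repeats <- .resolve(config$repeats, readRepeatMasker)
  fragile <- .resolve(config$fragileSites, readBedIntervals)

  # --- spot classification and sampling -------------------------------
  spots <- classifySpots(map, config$hotMin, config$midLo, config$midHi,
                         config$coldVal)
  note("classified spots: hot %d, middle %d, cold %d",
       length(spots$hot), length(spots$middle), length(spots$cold))
  sampleN <- if (is.null(config$sampleN)) length(spots$hot)
             else as.integer(config$sampleN)
  for (lbl in c("middle", "cold")) {
    avail <- length(spots[[lbl]])
    n <- min(sampleN, avail)
    if (n < sampleN)
      note("only %d %s spots available for a sample of %d; using %d",
           avail, lbl, sampleN, n)
    spots[[lbl]] <- sampleSpots(spots[[lbl]], n,
                                seed = childSeed(config$seed,
                                                 match(lbl, c("middle",
                                                              "cold"))))
  }
  note("sampled %d middle and %d cold spots", length(spots$middle),
       length(spots$cold))

  # --- spot-intersected gene sets -------------------------------------
  spotGenes <- lapply(spots, function(ss) {
    hit <- IRanges::overlapsAny(tx, ss, minoverlap = config$minOverlap,
                                ignore.strand = TRUE)
    list(transcripts = mcols(tx)$transcript_id[hit],
         symbols = sort(unique(mcols(tx)$gene_symbol[hit])))
  })
  names(spotGenes) <- c("HI", "MI", "CI")
  for (nm in names(spotGenes))
    note("%s: %d transcripts, %d genes", nm,
         length(spotGenes[[nm]]$transcripts),
         length(spotGenes[[nm]]$symbols))
  hi <- spotGenes$HI$symbols
  background <- sort(unique(mcols(tx)$gene_symbol))

  # --- HI region coverage ---------------------------------------------
  coverage <- NULL
  hiRegions <- NULL
  if (length(hi)) {
    hiRegions <- mergeTranscripts(
      tx[mcols(tx)$transcript_id %in% spotGenes$HI$transcripts])
    recs <- intersectSpots(hiRegions, spots$hot, config$minOverlap)
    coverage <- coverageSummary(recs, hiRegions, config$coveredThreshold)
    note("HI transcripts merge to %d regions; %d intersected",
         length(hiRegions), coverage$n_intersected)
  } else skip("coverage", "empty HI set")

  # --- gene-set enrichment --------------------------------------------
  setEnrichment <- NULL
  if (!is.null(sets) && length(sets) && length(hi)) {
    rows <- list()
    for (nm in names(sets)) {
      row <- runOptional(paste0("enrichment:", nm),
                         enrichTest(hi, sets[[nm]], background,
                                    queryName = "HI", targetName = nm))
      if (!is.null(row)) rows[[nm]] <- row
    }
    if (length(rows)) {
      setEnrichment <- do.call(rbind, rows)
      rownames(setEnrichment) <- NULL
      setEnrichment$q <- bhFdr(setEnrichment$p)
    }
  } else skip("gene_set_enrichment",
              if (length(hi)) "no gene sets supplied" else "empty HI set")

  # --- evolutionary-rate comparisons ----------------------------------
  rateComparisons <- NULL
  if (!is.null(rates) && nrow(rates) && length(hi)) {
    comps <- list()
    for (nm in intersect(config$rateCompareSets, names(sets))) {
      cmp <- runOptional(paste0("rates:", nm),
                         compareRates(hi, sets[[nm]], rates,
                                      exclusionMode = "pairwise_vs_reference",
                                      setNames = c("HI", nm)))
      if (!is.null(cmp)) {
        cmp$comparison <- paste0("HI_vs_", nm)
        comps[[nm]] <- cmp
      }
    }
    uni <- runOptional("rates:unique_only", excludeCommon(
      list(HI = hi, MI = spotGenes$MI$symbols, CI = spotGenes$CI$symbols),
      mode = "unique_only"))
    if (!is.null(uni)) {
      for (nm in c("MI", "CI")) {
        cmp <- runOptional(paste0("rates:", nm),
                           compareRates(uni$HI, uni[[nm]], rates,
                                        exclusionMode = "none",
                                        setNames = c("HI", nm)))
        if (!is.null(cmp)) {
          cmp$comparison <- paste0("HI_vs_", nm)
          comps[[nm]] <- cmp
        }
      }
    }
    if (length(comps)) {
      rateComparisons <- do.call(rbind, comps)
      rownames(rateComparisons) <- NULL
      rateComparisons <-
        rateComparisons[, c("comparison", "metric", "n_a", "n_b",
                            "direction", "p", "note")]
    }
  } else skip("rate_comparisons",
              if (length(hi)) "no rate table supplied" else "empty HI set")

  # --- duplicated-gene proportion (HI vs HK transcripts) --------------
  dgdProportion <- NULL
  if (!is.null(sets) && all(c("DGD", "HK") %in% names(sets)) &&
      length(spotGenes$HI$transcripts)) {
    dgd <- sets$DGD
    hiTxSym <- mcols(tx)$gene_symbol[mcols(tx)$transcript_id %in%
                                       spotGenes$HI$transcripts]
    hkTxSym <- mcols(tx)$gene_symbol[mcols(tx)$gene_symbol %in% sets$HK]
    dgdProportion <- runOptional("dgd_proportion",
      proportionTest(sum(hiTxSym %in% dgd), length(hiTxSym),
                     sum(hkTxSym %in% dgd), length(hkTxSym)))
    if (!is.null(dgdProportion))
      dgdProportion <- cbind(data.frame(comparison = "HI_vs_HK_transcripts",
                                        member_set = "DGD",
                                        stringsAsFactors = FALSE),
                             dgdProportion)
  } else skip("dgd_proportion", "needs DGD and HK sets and HI transcripts")

  # --- branch enrichment ----------------------------------------------
  branch <- NULL
  if (!is.null(branches) && length(branches) && length(hi)) {
    branch <- runOptional("branch_enrichment",
                          branchEnrichment(hi, branches, background))
  } else skip("branch_enrichment",
              if (length(hi)) "no branch assignment supplied"
              else "empty HI set")

  # --- motif enrichment ------------------------------------------------
  motifTable <- NULL
  if (!is.null(sequences) && length(sequences)) {
    cls <- S4Vectors::metadata(sequences)$region_class
    if (is.null(cls)) {
      skip("motif_enrichment", "sequences carry no region_class metadata")
    } else {
      qa <- sequences[cls == "HI"]
      qb <- sequences[cls == "background"]
      if (length(qa) && length(qb)) {
        rows <- lapply(config$motifs, function(m)
          runOptional(paste0("motif:", m), motifRegionEnrichment(qa, qb, m)))
        rows <- rows[!vapply(rows, is.null, logical(1L))]
        if (length(rows)) {
          motifTable <- do.call(rbind, rows)
          motifTable$q <- bhFdr(motifTable$p)
        }
      } else skip("motif_enrichment", "need both HI and background classes")
    }
  } else skip("motif_enrichment", "no region sequences supplied")

  # --- repeat enrichment ----------------------------------------------
  repeatTable <- NULL
  if (!is.null(repeats) && length(repeats) && length(spots$hot)) {
    extent <- unlist(range(GenomicRanges::split(
      granges(map), seqnames(map))))
    complement <- GenomicRanges::setdiff(extent, granges(spots$hot),
                                         ignore.strand = TRUE)
    repeatTable <- runOptional("repeat_enrichment",
      suppressMessages(repeatEnrichment(repeats, granges(spots$hot),
                                        complement, fdr = config$fdr)))
  } else skip("repeat_enrichment",
              if (length(spots$hot)) "no repeat annotation supplied"
              else "empty hot set")

  # --- fragile-site census --------------------------------------------
  fragileCensus <- NULL
  if (!is.null(fragile) && length(fragile) &&
      length(spotGenes$HI$transcripts)) {
    hiTx <- tx[mcols(tx)$transcript_id %in% spotGenes$HI$transcripts]
    fragileCensus <- overlapCensus(fragile, hiTx)
  } else skip("fragile_census", "needs fragile sites and HI transcripts")

  # --- pooled findings -------------------------------------------------
  pool <- list()
  if (!is.null(setEnrichment))
    pool$gene_set <- data.frame(analysis = "gene_set",
                                name = setEnrichment$target,
                                fe = setEnrichment$fe,
                                p = setEnrichment$p,
                                stringsAsFactors = FALSE)
  if (!is.null(branch))
    pool$branch <- data.frame(analysis = "branch",
                              name = sprintf("branch%d",
                                             branch$table$branch),
                              fe = branch$table$fe, p = branch$table$p,
                              stringsAsFactors = FALSE)
  if (!is.null(motifTable))
    pool$motif <- data.frame(analysis = "motif", name = motifTable$motif,
                             fe = motifTable$fe, p = motifTable$p,
                             stringsAsFactors = FALSE)
  if (!is.null(repeatTable) && nrow(repeatTable))
    pool$repeat_element <- data.frame(analysis = "repeat_element",
                                      name = repeatTable$element_name,
                                      fe = repeatTable$fe,
                                      p = repeatTable$p,
                                      stringsAsFactors = FALSE)
  findings <- NULL
  if (length(pool)) {
    all_tests <- do.call(rbind, pool)
    rownames(all_tests) <- NULL
    all_tests$q <- bhFdr(all_tests$p)
    findings <- all_tests[all_tests$q < config$fdr, , drop = FALSE]
    note("%d of %d pooled batch hypotheses significant at FDR %.3g",
         nrow(findings), nrow(all_tests), config$fdr)
  }

  provenance <- list(package = "recspot",
                     version = as.character(utils::packageVersion("recspot")),
                     seed = config$seed,
                     thresholds = config[c("hotMin", "midLo", "midHi",
                                           "coldVal", "minOverlap",
                                           "fdr", "coveredThreshold")],
                     sample_n = sampleN,
                     config_hash = .configHash(config))
  structure(list(spots = spots, spotGenes = spotGenes,
                 hiRegions = hiRegions, coverage = coverage,
                 setEnrichment = setEnrichment,
                 rateComparisons = rateComparisons,
                 dgdProportion = dgdProportion, branch = branch,
                 motifTable = motifTable, repeatTable = repeatTable,
                 fragileCensus = fragileCensus, findings = findings,
                 skipped = skipped, log = log, provenance = provenance),
            class = "recspotReport")
}

.configHash <- function(config) {
  keep <- config[c("hotMin", "midLo", "midHi", "coldVal", "minOverlap",
                   "sampleN", "fdr", "coveredThreshold", "motifs",
                   "rateCompareSets", "seed")]
  paths <- vapply(config[c("map", "genes", "sets", "rates", "branches",
                           "sequences", "repeats", "fragileSites")],
                  function(x) if (is.character(x)) x else class(x)[1L],
                  character(1L))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(c(keep, as.list(paths)), auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.recspotReport <- function(x, ...) {
  cat("recspot analysis report\n")
  cat(sprintf("  HI/MI/CI genes: %d/%d/%d\n",
              length(x$spotGenes$HI$symbols),
              length(x$spotGenes$MI$symbols),
              length(x$spotGenes$CI$symbols)))
  if (!is.null(x$coverage))
    cat(sprintf("  HI regions: %d (%.0f%% contain a full hotspot)\n",
                x$coverage$n_regions, 100 * x$coverage$fraction_full_spot))
  if (!is.null(x$findings))
    cat(sprintf("  findings at FDR: %d\n", nrow(x$findings)))
  if (length(x$skipped))
    cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes one TSV per result table, the HI/MI/CI gene lists, a
#' machine-readable \code{summary.json} (counts, coverage, fragile
#' census, skipped stages, provenance) and \code{run.log}. File ordering
#' is deterministic, and two runs with the same configuration and seed
#' produce identical contents.
#'
#' @param report a \code{recspotReport}.
#' @param outDir output directory (created if needed).
#' @return a data.frame manifest (\code{file}, \code{bytes}), invisibly
#'   ordered by file name.
#' @export
writeReport <- function(report, outDir) {
  stopifnot(inherits(report, "recspotReport"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  putTable <- function(df, fname) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    utils::write.table(df, file.path(outDir, fname), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <<- c(written, fname)
  }
  putLines <- function(lines, fname) {
    writeLines(lines, file.path(outDir, fname))
    written <<- c(written, fname)
  }
  for (nm in c("HI", "MI", "CI"))
    putLines(report$spotGenes[[nm]]$symbols,
             sprintf("%s_genes.txt", tolower(nm)))
  putTable(report$setEnrichment, "set_enrichment.tsv")
  putTable(report$rateComparisons, "rate_comparisons.tsv")
  putTable(report$dgdProportion, "dgd_proportion.tsv")
  if (!is.null(report$branch))
    putTable(report$branch$table, "branch_enrichment.tsv")
  putTable(report$motifTable, "motif_enrichment.tsv")
  putTable(report$repeatTable, "repeat_enrichment.tsv")
  putTable(report$findings, "findings.tsv")
  summary <- list(
    counts = list(
      hot_spots = length(report$spots$hot),
      middle_spots = length(report$spots$middle),
      cold_spots = length(report$spots$cold),
      hi_genes = length(report$spotGenes$HI$symbols),
      mi_genes = length(report$spotGenes$MI$symbols),
      ci_genes = length(report$spotGenes$CI$symbols),
      hi_transcripts = length(report$spotGenes$HI$transcripts),
      findings = if (is.null(report$findings)) 0L
                 else nrow(report$findings)),
    coverage = report$coverage,
    fragile_census = report$fragileCensus,
    branch0_fraction = if (is.null(report$branch)) NULL
                       else report$branch$branch0_fraction,
    skipped = as.list(report$skipped),
    provenance = report$provenance)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  written <- c(written, "summary.json")
  putLines(report$log, "run.log")
  written <- sort(unique(written))
  manifest <- data.frame(file = written,
                         bytes = file.size(file.path(outDir, written)),
                         stringsAsFactors = FALSE)
  invisible(manifest)
}
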