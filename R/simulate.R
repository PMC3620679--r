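#' Synthetic genome and analysis-input generator
#'
#' Configuration for the synthetic genome on which all generated inputs
#' live. The defaults mirror the shape of the human autosomal analysis at
#' roughly one-tenth scale (about 8,000 map windows of 10 kb, 1,800
#' protein-coding genes, and an expected 400 hotspots at the default
#' hotspot fraction) so a full run finishes in seconds.
#'
#' @param nChromosomes number of synthetic autosomes.
#' @param chromosomeLength length of each autosome in bases.
#' @param windowSize recombination-map window width in bases (default
#'   10,000, the map resolution).
#' @param nGenes number of genes to place.
#' @param geneMeanLength median gene length in bases (lognormal law).
#' @param geneLengthSdlog lognormal sdlog of gene length.
#' @param maxTranscripts transcripts per gene are drawn uniformly from
#'   1..maxTranscripts.
#' @return a \code{list} of class \code{recspotSimConfig}.
#' @export
simConfig <- function(nChromosomes = 4L, chromosomeLength = 2e7,
                      windowSize = 1e4, nGenes = 1800L,
                      geneMeanLength = 2e4, geneLengthSdlog = 0.6,
                      maxTranscripts = 4L) {
  cfg <- list(nChromosomes = as.integer(nChromosomes),
              chromosomeLength = as.numeric(chromosomeLength),
              windowSize = as.numeric(windowSize),
              nGenes = as.integer(nGenes),
              geneMeanLength = as.numeric(geneMeanLength),
              geneLengthSdlog = as.numeric(geneLengthSdlog),
              maxTranscripts = as.integer(maxTranscripts))
  if (cfg$nChromosomes < 1L || cfg$chromosomeLength < cfg$windowSize)
    stop("invalid genome dimensions")
  if (cfg$nGenes * cfg$geneMeanLength >
      0.8 * cfg$nChromosomes * cfg$chromosomeLength)
    stop("genome too small for the requested number of genes")
  class(cfg) <- "recspotSimConfig"
  cfg
}

.chromNames <- function(cfg) sprintf("chr%d", seq_len(cfg$nChromosomes))

#' Generate a synthetic recombination map
#'
#' Tiles each chromosome with fixed-width windows (a short last window
#' where the length is not divisible by the resolution) and draws each
#' window's SRR from a three-part mixture: with probability
#' \code{hotspotFraction} a hot draw with support strictly above 10
#' (shifted lognormal); otherwise an atom at 0 with mass \code{coldMass}
#' or a low-rate draw on (0, 10] skewed toward small values
#' (\code{10 * U^2} for uniform U), so the default thresholds yield
#' non-trivial hot, middle and cold sets.
#'
#' @param config a [simConfig()].
#' @param hotspotFraction probability a window is hot; default 0.05.
#' @param coldMass probability mass of SRR exactly 0 among non-hot
#'   windows; default 0.3.
#' @param seed integer seed; the map is a pure function of
#'   (config, arguments, seed).
#' @return a list with \code{map} (a [RecombMap]) and \code{truth}
#'   (the generating parameters, including the realized hot count).
#' @export
genRecombMap <- function(config = simConfig(), hotspotFraction = 0.05,
                         coldMass = 0.3, seed = NULL) {
  stopifnot(inherits(config, "recspotSimConfig"))
  if (!(hotspotFraction > 0 && hotspotFraction < 1) &&
      hotspotFraction != 0)
    stop("'hotspotFraction' must lie in [0, 1)")
  withSeed(seed, {
    pieces <- lapply(.chromNames(config), function(chr) {
      starts <- seq(0, config$chromosomeLength - 1, by = config$windowSize)
      ends <- pmin(starts + config$windowSize, config$chromosomeLength)
      data.frame(chrom = chr, start = starts, end = ends)
    })
    df <- do.call(rbind, pieces)
    n <- nrow(df)
    hot <- stats::runif(n) < hotspotFraction
    srr <- numeric(n)
    srr[hot] <- 10 + stats::rlnorm(sum(hot), meanlog = 1, sdlog = 0.5)
    nonhot <- which(!hot)
    coldDraw <- stats::runif(length(nonhot)) < coldMass
    srr[nonhot[coldDraw]] <- 0
    warm <- nonhot[!coldDraw]
    srr[warm] <- 10 * stats::runif(length(warm))^2
    map <- RecombMap(grFromBed0(df$chrom, df$start, df$end), srr = srr)
    list(map = map,
         truth = list(seed = seed, hotspot_fraction = hotspotFraction,
                      cold_mass = coldMass, n_windows = n,
                      n_hot_windows = sum(hot)))
  })
}

#' Generate synthetic transcript models
#'
#' Places genes on the synthetic genome with optionally biased placement
#' relative to hotspot windows: with bias \code{b}, the odds of a gene's
#' midpoint landing in a hot window (SRR > \code{hotMin}) are multiplied
#' by \code{b}; \code{b = 1} is placement independent of the map and
#' \code{b = 0} forbids any overlap with hot windows (rejection
#' sampling). Each gene gets 1..maxTranscripts transcripts that share the
#' gene core (nested/overlapping), the first spanning the whole gene.
#'
#' @param config a [simConfig()].
#' @param map the [RecombMap] the genes are placed against.
#' @param hotspotBias placement odds multiplier for hot windows
#'   (>= 0); default 1.
#' @param hotMin hotspot threshold used for the bias; default 10.
#' @param seed integer seed.
#' @return a sorted \code{GRanges} with metadata columns
#'   \code{transcript_id} and \code{gene_symbol}.
#' @export
genGeneAnnotation <- function(config = simConfig(), map, hotspotBias = 1,
                              hotMin = 10, seed = NULL) {
  stopifnot(inherits(config, "recspotSimConfig"), is(map, "GRanges"))
  if (hotspotBias < 0) stop("'hotspotBias' must be >= 0")
  withSeed(seed, {
    hotWin <- granges(map)[srr(map) > hotMin]
    w <- ifelse(srr(map) > hotMin, hotspotBias, 1)
    if (all(w == 0)) stop("no window has positive placement weight")
    lens <- pmax(200, round(stats::rlnorm(config$nGenes,
                                          log(config$geneMeanLength),
                                          config$geneLengthSdlog)))
    if (any(lens >= config$chromosomeLength))
      lens <- pmin(lens, config$chromosomeLength - 1)
    placeOnce <- function(k, lenk) {
      wi <- sample.int(length(map), k, replace = TRUE, prob = w)
      mid <- start(map)[wi] +
        floor(stats::runif(k) * GenomicRanges::width(map)[wi])
      st <- pmin(pmax(mid - floor(lenk / 2), 1),
                 config$chromosomeLength - lenk + 1)
      GenomicRanges::GRanges(as.character(seqnames(map))[wi],
                             IRanges::IRanges(st, width = lenk))
    }
    genes <- placeOnce(config$nGenes, lens)
    if (hotspotBias == 0 && length(hotWin)) {
      for (iter in 1:200) {
        bad <- which(IRanges::overlapsAny(genes, hotWin,
                                          ignore.strand = TRUE))
        if (!length(bad)) break
        genes[bad] <- placeOnce(length(bad), lens[bad])
        if (iter == 200)
          stop("could not place genes clear of hot windows; genome too hot")
      }
    }
    syms <- sprintf("G%05d", seq_len(config$nGenes))
    ntx <- sample.int(config$maxTranscripts, config$nGenes, replace = TRUE)
    rows <- lapply(seq_len(config$nGenes), function(i) {
      gl <- GenomicRanges::width(genes)[i]
      jit <- floor(stats::runif(2 * ntx[i]) * 0.25 * gl)
      st <- start(genes)[i] + c(0L, jit[seq_len(ntx[i] - 1)])
      en <- end(genes)[i] - c(0L, jit[ntx[i] - 1 + seq_len(ntx[i] - 1)])
      data.frame(chrom = as.character(seqnames(genes))[i],
                 start = st, end = pmax(en, st + 49L),
                 transcript_id = sprintf("%s.t%d", syms[i], seq_len(ntx[i])),
                 gene_symbol = syms[i], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    mcols(gr)$transcript_id <- df$transcript_id
    mcols(gr)$gene_symbol <- df$gene_symbol
    sort(gr, ignore.strand = TRUE)
  })
}

#' Generate gene sets with planted fold enrichments
#'
#' For a set with planted enrichment \code{f} and target size \code{s}
#' over a background of \code{N} genes of which \code{H} are in the query
#' (e.g. hotspot-intersected) set, membership is Bernoulli with
#' probability \code{f * p0} for query genes and \code{p0} for the rest,
#' where \code{p0 = s / (H f + N - H)} hits the target size in
#' expectation. \code{f = 1} plants independence; \code{f < 1} plants
#' depletion.
#'
#' @param annotation transcript \code{GRanges} with a \code{gene_symbol}
#'   column, or a plain character vector of background symbols.
#' @param hiSymbols character vector: the query (HI-like) gene symbols.
#' @param plantedFe named numeric vector of planted enrichments (> 0),
#'   one per set.
#' @param setSizes named numeric vector of target set sizes (same names).
#' @param seed integer seed.
#' @return a list with \code{sets} (named list of symbol vectors) and
#'   \code{truth} (planted parameters plus realized sizes and overlaps).
#' @export
genGeneSets <- function(annotation, hiSymbols, plantedFe, setSizes,
                        seed = NULL) {
  bg <- if (is(annotation, "GRanges"))
    unique(mcols(annotation)$gene_symbol) else normalizeSymbols(annotation)
  hi <- intersect(normalizeSymbols(hiSymbols), bg)
  N <- length(bg); H <- length(hi)
  if (!N) stop("empty background")
  nms <- names(setSizes)
  if (is.null(nms) || !all(nms %in% names(plantedFe) | TRUE))
    stopifnot(!is.null(nms))
  isHi <- bg %in% hi
  withSeed(seed, {
    sets <- list(); realized <- list()
    for (nm in nms) {
      f <- if (nm %in% names(plantedFe)) plantedFe[[nm]] else 1
      s <- setSizes[[nm]]
      if (!is.finite(f) || f <= 0)
        stop(sprintf("planted fe for set '%s' must be > 0", nm))
      p0 <- s / (H * f + N - H)
      if (p0 > 1 || f * p0 > 1)
        stop(sprintf("infeasible fe/size combination for set '%s'", nm))
      p <- ifelse(isHi, f * p0, p0)
      member <- stats::runif(N) < p
      sets[[nm]] <- bg[member]
      realized[[nm]] <- data.frame(set = nm, planted_fe = f,
                                   target_size = s, size = sum(member),
                                   overlap_hi = sum(member & isHi),
                                   stringsAsFactors = FALSE)
    }
    list(sets = sets,
         truth = list(seed = seed, planted_fe = as.list(plantedFe),
                      set_sizes = as.list(setSizes),
                      n_background = N, n_hi = H,
                      realized = do.call(rbind, realized)))
  })
}

#' Generate a per-gene evolutionary-rate table with planted shifts
#'
#' Draws baseline (dN, dS) per background gene from lognormal laws with
#' realistic human-mouse magnitudes (median dN 0.07, median dS 0.5, with
#' a small zero-inflation of dS so some genes lack a defined dN/dS), then
#' applies per-set additive shifts: a gene in a shifted set gets
#' \code{dn + delta} and \code{ds + 2 * delta} (floored at 0), which
#' moves dN, dS and dN/dS in the direction of \code{delta} under the
#' default law. Genes in several shifted sets take the first set in the
#' order of \code{rateShifts} (the priority list).
#'
#' @param background character vector of all gene symbols.
#' @param sets named list of gene-symbol vectors (the shifted sets must
#'   appear here).
#' @param rateShifts named numeric vector of per-set dN shifts; names
#'   order is the priority order for genes in several sets.
#' @param dnMeanlog,dnSdlog,dsMeanlog,dsSdlog baseline lognormal
#'   parameters.
#' @param dsZeroProb probability of dS drawn exactly 0; default 0.02.
#' @param seed integer seed.
#' @return a data.frame with columns \code{gene_symbol, dn, ds, dnds}
#'   (dnds is \code{NA} where ds is 0).
#' @export
genRateTable <- function(background, sets = list(), rateShifts = numeric(0),
                         dnMeanlog = log(0.07), dnSdlog = 0.7,
                         dsMeanlog = log(0.5), dsSdlog = 0.4,
                         dsZeroProb = 0.02, seed = NULL) {
  bg <- normalizeSymbols(background)
  n <- length(bg)
  withSeed(seed, {
    dn <- stats::rlnorm(n, dnMeanlog, dnSdlog)
    ds <- stats::rlnorm(n, dsMeanlog, dsSdlog)
    ds[stats::runif(n) < dsZeroProb] <- 0
    shift <- numeric(n)
    assigned <- logical(n)
    for (nm in names(rateShifts)) {
      if (rateShifts[[nm]] == 0) next
      if (!nm %in% names(sets))
        stop(sprintf("rate shift given for unknown set '%s'", nm))
      sel <- !assigned & bg %in% normalizeSymbols(sets[[nm]])
      shift[sel] <- rateShifts[[nm]]
      assigned <- assigned | sel
    }
    dn <- pmax(dn + shift, 0)
    ds <- pmax(ds + 2 * shift, 0)
    data.frame(gene_symbol = bg, dn = dn, ds = ds,
               dnds = ifelse(ds > 0, dn / ds, NA_real_),
               stringsAsFactors = FALSE)
  })
}

#' Generate an evolutionary-age branch assignment
#'
#' Assigns branches 0 (oldest) through 12 (primate-specific young) to
#' background genes, with separately controllable branch-0 probability
#' for the query (HI-like) genes; the remaining mass decays
#' geometrically over branches 1..12.
#'
#' @param background character vector of background symbols.
#' @param hiSymbols query symbols.
#' @param branch0Background,branch0Hi branch-0 probabilities for
#'   non-query and query genes.
#' @param coverage fraction of background genes that receive an
#'   assignment at all (age catalogues are incomplete); default 0.9.
#' @param seed integer seed.
#' @return a named integer vector of branches.
#' @export
genBranchAssignment <- function(background, hiSymbols,
                                branch0Background = 0.55, branch0Hi = 0.8,
                                coverage = 0.9, seed = NULL) {
  bg <- normalizeSymbols(background)
  hi <- normalizeSymbols(hiSymbols)
  withSeed(seed, {
    keep <- stats::runif(length(bg)) < coverage
    bg <- bg[keep]
    p0 <- ifelse(bg %in% hi, branch0Hi, branch0Background)
    br <- integer(length(bg))
    old <- stats::runif(length(bg)) < p0
    tail_probs <- 0.6^(1:12); tail_probs <- tail_probs / sum(tail_probs)
    br[!old] <- sample(1:12, sum(!old), replace = TRUE, prob = tail_probs)
    stats::setNames(br, bg)
  })
}

.DEFAULT_MOTIFS <- c("CCTCCCT", "CCCCACCCC", "CCNCCNTNNCCNC")

#' Generate region sequences and repeat annotations with planted effects
#'
#' \strong{Sequences}: for every region, an i.i.d. uniform A/C/G/T
#' sequence of \code{seqLength} bases (or the region width if shorter);
#' for each motif, with the class-specific probability
#' \code{motifRates[[class]][motif]} one instance (N positions filled
#' with random bases) is written at a uniform position. Motifs longer
#' than a region are skipped with a message. Note that short motifs also
#' occur by chance in random sequence; planted rates sit on top of that
#' baseline.
#'
#' \strong{Repeats}: instances of each element are placed as a marked
#' point process: the per-base intensity in class-B regions is
#' \code{baseIntensity}, and \code{repeatDensityRatio[element]} times
#' that in class-A regions, with instance lengths uniform on 150..300.
#'
#' @param regions a \code{GRanges} with \code{region_id} and
#'   \code{region_class} metadata columns.
#' @param motifRates named list: class -> named numeric vector
#'   (motif -> per-region presence probability); \code{NULL} skips
#'   sequence generation.
#' @param repeatDensityRatio named numeric vector (element -> A:B density
#'   ratio); \code{NULL} skips repeat generation.
#' @param classA,classB the two region classes compared by the repeat
#'   process.
#' @param seqLength sequence length generated per region; default 1000.
#' @param baseIntensity class-B repeat intensity per base; default 5e-5
#'   (one instance per 20 kb).
#' @param seed integer seed.
#' @return a list with \code{sequences} (a named \code{DNAStringSet} with
#'   \code{region_class} in its metadata, or \code{NULL}), \code{repeats}
#'   (a \code{GRanges} with \code{element_name}, or \code{NULL}) and
#'   \code{truth}.
#' @export
genSequencesAndRepeats <- function(regions, motifRates = NULL,
                                   repeatDensityRatio = NULL,
                                   classA = "A", classB = "B",
                                   seqLength = 1000L, baseIntensity = 5e-5,
                                   seed = NULL) {
  stopifnot(is(regions, "GRanges"))
  cls <- mcols(regions)$region_class
  ids <- mcols(regions)$region_id
  if (is.null(cls) || is.null(ids))
    stop("'regions' needs 'region_id' and 'region_class' metadata columns")
  withSeed(seed, {
    sequences <- NULL
    if (!is.null(motifRates)) {
      lens <- pmin(GenomicRanges::width(regions), as.integer(seqLength))
      seqs <- vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1L))
      for (i in seq_along(seqs)) {
        rates <- motifRates[[cls[i]]]
        if (is.null(rates)) next
        for (m in names(rates)) {
          if (stats::runif(1) >= rates[[m]]) next
          mlen <- nchar(m)
          if (mlen > lens[i]) {
            message(sprintf("motif %s longer than region %s; skipped",
                            m, ids[i]))
            next
          }
          inst <- strsplit(m, "")[[1L]]
          npos <- inst == "N"
          inst[npos] <- sample(c("A", "C", "G", "T"), sum(npos),
                               replace = TRUE)
          at <- sample.int(lens[i] - mlen + 1L, 1L)
          substr(seqs[i], at, at + mlen - 1L) <- paste(inst, collapse = "")
        }
      }
      sequences <- Biostrings::DNAStringSet(seqs)
      names(sequences) <- ids
      S4Vectors::metadata(sequences)$region_class <- cls
    }
    repeats <- NULL
    if (!is.null(repeatDensityRatio)) {
      placeIn <- function(regs, nInst) {
        if (nInst == 0L || !length(regs))
          return(GenomicRanges::GRanges())
        wi <- sample.int(length(regs), nInst, replace = TRUE,
                         prob = GenomicRanges::width(regs))
        off <- floor(stats::runif(nInst) * GenomicRanges::width(regs)[wi])
        ilen <- 150L + floor(stats::runif(nInst) * 151)
        st <- start(regs)[wi] + off
        GenomicRanges::GRanges(as.character(seqnames(regs))[wi],
                               IRanges::IRanges(st, width = ilen))
      }
      regsA <- regions[cls == classA]
      regsB <- regions[cls == classB]
      basesA <- sum(GenomicRanges::width(regsA))
      basesB <- sum(GenomicRanges::width(regsB))
      parts <- list()
      for (e in names(repeatDensityRatio)) {
        r <- repeatDensityRatio[[e]]
        nA <- stats::rpois(1, r * baseIntensity * basesA)
        nB <- stats::rpois(1, baseIntensity * basesB)
        gr <- c(placeIn(regsA, nA), placeIn(regsB, nB))
        if (length(gr)) {
          mcols(gr)$element_name <- e
          mcols(gr)$family <- "synthetic"
          parts[[e]] <- gr
        }
      }
      repeats <- if (length(parts))
        sort(do.call(c, unname(parts)), ignore.strand = TRUE)
      else GenomicRanges::GRanges()
    }
    list(sequences = sequences, repeats = repeats,
         truth = list(seed = seed,
                      motif_rates = motifRates,
                      repeat_density_ratio = as.list(repeatDensityRatio),
                      seq_length = seqLength,
                      base_intensity = baseIntensity))
  })
}

#' Generate fragile-site intervals
#'
#' @param config a [simConfig()].
#' @param nSites number of sites; default 12.
#' @param siteLength site length in bases; default 5e5 (fragile sites are
#'   broad, megabase-scale bands at full scale).
#' @param seed integer seed.
#' @return a sorted \code{GRanges} with a \code{name} column.
#' @export
genFragileSites <- function(config = simConfig(), nSites = 12L,
                            siteLength = 5e5, seed = NULL) {
  withSeed(seed, {
    chr <- sample(.chromNames(config), nSites, replace = TRUE)
    st <- 1 + floor(stats::runif(nSites) *
                      (config$chromosomeLength - siteLength))
    gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(st,
                                                       width = siteLength))
    mcols(gr)$name <- sprintf("FRA%d", seq_len(nSites))
    sort(gr, ignore.strand = TRUE)
  })
}
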