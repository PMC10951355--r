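# Seeded generator of synthetic pipeline inputs with the statistical
# structure the analyses assume: binned cis loops with integer contact
# counts, two promoter classes differing in edge multiplicity and weight,
# planted hub CREs, a chromatin-state track with super-enhancers enriched on
# the high-weight partners of memory promoters, expression monotonically
# coupled to connectivity, and a primed/naive nascent-response design.

#' Parameters of the synthetic interactome generator
#'
#' Defaults define the standard simulated study: two 25 Mb chromosomes tiled
#' into 10 kb bins, 300 genes (100 memory / 100 responsive / 100
#' nonresponsive) each owning a disjoint 16-bin territory so that
#' interconnected domains stay local; memory promoters are wired by many
#' low-weight edges (mean 8 edges of mean weight 2) and responsive promoters
#' by few heavy ones (mean 2 edges of mean weight 8); a fraction of memory
#' promoters additionally carries one heavy edge whose partner bin hosts a
#' super-enhancer with probability \code{seOnMemoryProb}; 10 hub CRE bins
#' receive 20 extra local edges each.
#'
#' @param seed Integer seed; the full bundle is a pure function of it.
#' @param binSize Bin width in bp.
#' @param nChromosomes,chromLength Genome shape.
#' @param nMemoryGenes,nResponsiveGenes,nOtherGenes Genes per response class.
#' @param memoryEdgeCountMean,responsiveEdgeCountMean,otherEdgeCountMean
#'   Poisson means of the per-promoter edge count.
#' @param memoryEdgeWeightMean,responsiveEdgeWeightMean,otherEdgeWeightMean
#'   Means of the shifted-Poisson (1 + Poisson(mean - 1)) contact counts.
#' @param memoryStrongEdgeProb Probability that a memory promoter carries one
#'   extra heavy edge (weight from the responsive distribution); these heavy
#'   partners are where super-enhancers are planted.
#' @param nHubCres,hubExtraEdges Planted hub CRE bins and their extra edges.
#' @param expressionCoupling Slope of log-mean expression on log1p
#'   connectivity (0 = no coupling).
#' @param baselineExpression Expression mean at zero connectivity.
#' @param nExprSamples Columns of the bulk expression table.
#' @param nascentDesign Per-class condition means (naive_veh, naive_atRA,
#'   primed_atRA) of the nascent table.
#' @param spikeinFactors Per-sample spike-in factors of the nascent table
#'   (2 replicates x 3 conditions).
#' @param seOnMemoryProb,seBackgroundProb Super-enhancer planting probability
#'   on heavy memory partners vs any other enhancer bin.
#' @param broadPeakProb Probability of a BroadPeak interval on a promoter bin.
#' @param noiseDispersion Log-normal sdlog of multiplicative noise.
#' @param nCells Columns of the single-cell matrix.
#' @param decoyLoopFraction Fraction of extra non-significant loops
#'   (q > 0.01) added to exercise the significance filter.
#' @return A validated parameter list of class \code{SimulationParams}.
#' @export
simulationParams <- function(seed = 1,
                             binSize = 10000,
                             nChromosomes = 2,
                             chromLength = 25e6,
                             nMemoryGenes = 100,
                             nResponsiveGenes = 100,
                             nOtherGenes = 100,
                             memoryEdgeCountMean = 8,
                             responsiveEdgeCountMean = 2,
                             otherEdgeCountMean = 3,
                             memoryEdgeWeightMean = 2,
                             responsiveEdgeWeightMean = 8,
                             otherEdgeWeightMean = 4,
                             memoryStrongEdgeProb = 0.3,
                             nHubCres = 10,
                             hubExtraEdges = 20,
                             expressionCoupling = 0.8,
                             baselineExpression = 20,
                             nExprSamples = 6,
                             nascentDesign = list(
                               memory = c(naive_veh = 10, naive_atRA = 25,
                                          primed_atRA = 60),
                               responsive = c(naive_veh = 10, naive_atRA = 25,
                                              primed_atRA = 27),
                               nonresponsive = c(naive_veh = 10,
                                                 naive_atRA = 10,
                                                 primed_atRA = 10)),
                             spikeinFactors = c(1, 1, 1.25, 1.25, 0.8, 0.8),
                             seOnMemoryProb = 0.6,
                             seBackgroundProb = 0.1,
                             broadPeakProb = 0.05,
                             noiseDispersion = 0.05,
                             nCells = 100,
                             decoyLoopFraction = 0.05) {
  p <- as.list(environment())
  stopifnot(p$binSize > 0, p$nChromosomes >= 1, p$chromLength >= p$binSize,
            p$nMemoryGenes >= 0, p$nResponsiveGenes >= 0, p$nOtherGenes >= 0,
            p$nHubCres >= 0, p$hubExtraEdges >= 0,
            p$expressionCoupling >= 0, p$noiseDispersion >= 0,
            length(p$spikeinFactors) == 6, all(p$spikeinFactors > 0))
  if (p$memoryEdgeCountMean <= p$responsiveEdgeCountMean)
    warning("memory promoters should carry more edges than responsive ones")
  if (p$memoryEdgeWeightMean >= p$responsiveEdgeWeightMean)
    warning("memory edges should be lighter than responsive ones")
  class(p) <- "SimulationParams"
  p
}

.territoryBins <- 16L  # bins per gene territory (1 promoter + 15 enhancers)

# shifted Poisson: integer weights >= 1 with the given mean
.rWeight <- function(n, mean) 1L + stats::rpois(n, max(mean - 1, 0))

#' Generate a synthetic input bundle
#'
#' Writes every input the pipeline reads (loops BEDPE, ATAC peaks, TSS table,
#' chromatin-state / super-enhancer / broad-peak BEDs, CRE set, bulk
#' expression, nascent expression with a spike-in sample sheet, single-cell
#' matrix, truth tables and a manifest) into \code{dir}, in exactly the
#' dialects the package readers parse. Identical seeds give byte-identical
#' bundles.
#'
#' @param params A \code{\link{simulationParams}} list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: params, scheme, paths (named file paths), and
#'   truth (genes data.frame, hubBins, sePlantedBins, promoterBins).
#' @export
simulateBundle <- function(params = simulationParams(), dir) {
  stopifnot(inherits(params, "SimulationParams"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withSeed(params$seed, .simulateBundleImpl(params, dir))
}

.simulateBundleImpl <- function(p, dir) {
  chroms <- paste0("chr", seq_len(p$nChromosomes))
  chromSizes <- structure(rep(p$chromLength, p$nChromosomes), names = chroms)
  scheme <- BinScheme(p$binSize, chromSizes)
  binsPerChrom <- as.integer(floor(p$chromLength / p$binSize))
  terPerChrom <- binsPerChrom %/% .territoryBins
  nGenes <- p$nMemoryGenes + p$nResponsiveGenes + p$nOtherGenes
  if (nGenes > terPerChrom * p$nChromosomes)
    stop("genome too small: ", nGenes, " genes need ",
         nGenes * .territoryBins, " bins, have ",
         binsPerChrom * p$nChromosomes)

  geneIds <- sprintf("G%04d", seq_len(nGenes))
  classes <- sample(rep(c("memory", "responsive", "nonresponsive"),
                        times = c(p$nMemoryGenes, p$nResponsiveGenes,
                                  p$nOtherGenes)))
  # consecutive 16-bin territories, never crossing a chromosome boundary
  terChrom <- chroms[(seq_len(nGenes) - 1L) %/% terPerChrom + 1L]
  terIdx <- (seq_len(nGenes) - 1L) %% terPerChrom
  terStartBin <- terIdx * .territoryBins
  promoterBinStart <- terStartBin * p$binSize
  strand <- sample(c("+", "-"), nGenes, replace = TRUE)
  tssPos <- promoterBinStart + 5000L
  tss <- data.frame(gene = geneIds, chrom = terChrom, tss = tssPos,
                    strand = strand, stringsAsFactors = FALSE)

  enhOffsets <- seq_len(.territoryBins - 1L)  # bins 1..15 of each territory

  countMean <- c(memory = p$memoryEdgeCountMean,
                 responsive = p$responsiveEdgeCountMean,
                 nonresponsive = p$otherEdgeCountMean)
  weightMean <- c(memory = p$memoryEdgeWeightMean,
                  responsive = p$responsiveEdgeWeightMean,
                  nonresponsive = p$otherEdgeWeightMean)

  loopRows <- list()
  heavyPartnerBins <- character(0)     # SE planting sites
  usedEnhancer <- list()               # per-gene partner bin starts
  for (i in seq_len(nGenes)) {
    cls <- classes[i]
    k <- stats::rpois(1, countMean[[cls]])
    k <- min(k, length(enhOffsets))
    partners <- integer(0)
    if (k > 0) {
      off <- sample(enhOffsets, k)
      partners <- (terStartBin[i] + off) * p$binSize
      w <- .rWeight(k, weightMean[[cls]])
      loopRows[[length(loopRows) + 1L]] <- data.frame(
        chrom = terChrom[i], a = promoterBinStart[i], b = partners,
        w = w, stringsAsFactors = FALSE)
    }
    if (cls == "memory" && stats::runif(1) < p$memoryStrongEdgeProb) {
      offLeft <- setdiff(enhOffsets, (partners / p$binSize) - terStartBin[i])
      if (length(offLeft)) {
        hb <- (terStartBin[i] + sample(offLeft, 1)) * p$binSize
        loopRows[[length(loopRows) + 1L]] <- data.frame(
          chrom = terChrom[i], a = promoterBinStart[i], b = hb,
          w = .rWeight(1, p$responsiveEdgeWeightMean),
          stringsAsFactors = FALSE)
        heavyPartnerBins <- c(heavyPartnerBins, .binId(terChrom[i], hb))
        partners <- c(partners, hb)
      }
    }
    usedEnhancer[[i]] <- partners
  }

  # planted hub CREs: enhancer bins with extra local edges
  allPartnerIds <- unique(unlist(lapply(seq_len(nGenes), function(i)
    .binId(terChrom[i], usedEnhancer[[i]]))))
  hubBins <- character(0)
  if (p$nHubCres > 0 && length(allPartnerIds) >= p$nHubCres) {
    hubBins <- sort(sample(allPartnerIds, p$nHubCres))
    for (hb in hubBins) {
      parts <- strsplit(hb, ":", fixed = TRUE)[[1]]
      hc <- parts[1]; hs <- as.numeric(parts[2])
      win <- seq(hs - 12 * p$binSize, hs + 12 * p$binSize, by = p$binSize)
      win <- win[win >= 0 & win < chromSizes[hc] & win != hs]
      tgt <- sample(win, min(p$hubExtraEdges, length(win)))
      loopRows[[length(loopRows) + 1L]] <- data.frame(
        chrom = hc, a = hs, b = tgt,
        w = .rWeight(length(tgt), p$memoryEdgeWeightMean),
        stringsAsFactors = FALSE)
    }
  }

  raw <- do.call(rbind, loopRows)
  lo <- pmin(raw$a, raw$b); hi <- pmax(raw$a, raw$b)
  key <- paste(raw$chrom, lo, hi)
  agg <- rowsum(raw$w, key)
  first <- !duplicated(key)
  loops <- data.frame(chrom = raw$chrom[first], a = lo[first], b = hi[first],
                      w = as.integer(agg[match(key[first], rownames(agg))]),
                      stringsAsFactors = FALSE)
  loops <- loops[order(loops$chrom, loops$a, loops$b), , drop = FALSE]
  loops$q <- stats::runif(nrow(loops), 1e-4, 0.009)

  # decoy non-significant pairs (filtered out at q <= 0.01)
  nDecoy <- round(p$decoyLoopFraction * nrow(loops))
  if (nDecoy > 0) {
    dChrom <- sample(chroms, nDecoy, replace = TRUE)
    dA <- sample.int(binsPerChrom, nDecoy, replace = TRUE) - 1L
    dB <- (dA + sample.int(20, nDecoy, replace = TRUE)) %% binsPerChrom
    keep <- dA != dB
    decoys <- data.frame(chrom = dChrom[keep],
                         a = pmin(dA, dB)[keep] * p$binSize,
                         b = pmax(dA, dB)[keep] * p$binSize,
                         w = .rWeight(sum(keep), 2),
                         q = stats::runif(sum(keep), 0.02, 0.5))
    loops <- rbind(loops, decoys)
  }

  loopTable <- data.frame(
    chrom1 = loops$chrom,
    start1 = loops$a, end1 = binEnd(scheme, loops$chrom, loops$a),
    chrom2 = loops$chrom,
    start2 = loops$b, end2 = binEnd(scheme, loops$chrom, loops$b),
    count = loops$w, q = loops$q, stringsAsFactors = FALSE)

  # ATAC peaks: one per promoter, one per territory enhancer bin
  promPeaks <- data.frame(chrom = terChrom, start = tssPos - 200L,
                          end = tssPos + 200L)
  enhRows <- do.call(rbind, lapply(seq_len(nGenes), function(i) {
    starts <- (terStartBin[i] + enhOffsets) * p$binSize
    data.frame(chrom = terChrom[i], start = starts + 4000L,
               end = starts + 4600L)
  }))
  peaks <- rbind(promPeaks, enhRows)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]

  # chromatin states: one background label per bin (hierarchy ranks 3-11)
  bgLevels <- stateLevels()[3:11]
  bgProb <- c(0.08, 0.10, 0.06, 0.10, 0.05, 0.05, 0.06, 0.15, 0.35)
  stateRows <- do.call(rbind, lapply(chroms, function(cc) {
    starts <- (seq_len(binsPerChrom) - 1L) * p$binSize
    data.frame(chrom = cc, start = starts,
               end = binEnd(scheme, cc, starts),
               state = sample(bgLevels, binsPerChrom, replace = TRUE,
                              prob = bgProb),
               stringsAsFactors = FALSE)
  }))

  # super-enhancers: heavy memory partners at seOnMemoryProb, any other
  # partner bin at the background probability
  seOnHeavy <- heavyPartnerBins[
    stats::runif(length(heavyPartnerBins)) < p$seOnMemoryProb]
  others <- setdiff(allPartnerIds, heavyPartnerBins)
  seBg <- others[stats::runif(length(others)) < p$seBackgroundProb]
  seBins <- sort(unique(c(seOnHeavy, seBg)))
  seRows <- .binIdToBed(seBins, scheme)

  # broad promoter-mark domains on a few promoter bins
  isBroad <- stats::runif(nGenes) < p$broadPeakProb
  broadRows <- data.frame(chrom = terChrom[isBroad],
                          start = promoterBinStart[isBroad],
                          end = binEnd(scheme, terChrom[isBroad],
                                       promoterBinStart[isBroad]))

  # CREs of interest = the planted hub bins
  creRows <- .binIdToBed(hubBins, scheme)

  # gene connectivity (sum of significant contact counts at the promoter bin)
  sig <- loopTable[loopTable$q <= 0.01, , drop = FALSE]
  pid <- .binId(terChrom, promoterBinStart)
  id1 <- .binId(sig$chrom1, sig$start1)
  id2 <- .binId(sig$chrom2, sig$start2)
  conn <- vapply(pid, function(b)
    sum(sig$count[id1 == b | id2 == b]), 0)

  # bulk expression: log-mean coupled to connectivity
  mu <- p$baselineExpression *
    exp(p$expressionCoupling * log1p(conn))
  exprM <- matrix(0, nGenes, p$nExprSamples,
                  dimnames = list(geneIds,
                                  sprintf("S%02d", seq_len(p$nExprSamples))))
  for (j in seq_len(p$nExprSamples)) {
    condBoost <- if (j > p$nExprSamples / 2)
      ifelse(classes == "memory", 1.5, 1.0) else 1.0
    exprM[, j] <- stats::rpois(
      nGenes, mu * condBoost *
        exp(stats::rnorm(nGenes, 0, p$noiseDispersion)))
  }

  # nascent expression, 2 replicates x 3 conditions; raw = value * factor
  conds <- rep(c("naive_veh", "naive_atRA", "primed_atRA"), each = 2)
  nasSamples <- paste0(conds, "_r", rep(1:2, 3))
  classMeans <- do.call(rbind, p$nascentDesign)[classes, , drop = FALSE]
  nasM <- matrix(0, nGenes, 6, dimnames = list(geneIds, nasSamples))
  for (j in 1:6) {
    true <- classMeans[, conds[j]] *
      exp(stats::rnorm(nGenes, 0, p$noiseDispersion))
    nasM[, j] <- true * p$spikeinFactors[j]
  }

  # single-cell matrix: memory genes elevated in half of the cells
  cellIds <- sprintf("C%03d", seq_len(p$nCells))
  memCell <- seq_len(p$nCells) <= p$nCells / 2
  lam <- matrix(2, nGenes, p$nCells)
  lam[classes == "memory", memCell] <- 8
  cellM <- matrix(stats::rpois(nGenes * p$nCells, lam), nGenes, p$nCells,
                  dimnames = list(geneIds, cellIds))

  # ---- write files ----
  paths <- list(
    loops = file.path(dir, "loops.bedpe"),
    atacPeaks = file.path(dir, "atac_peaks.bed"),
    tss = file.path(dir, "tss.tsv"),
    states = file.path(dir, "states.bed"),
    superEnhancers = file.path(dir, "super_enhancers.bed"),
    broadPeaks = file.path(dir, "broad_peaks.bed"),
    creSet = file.path(dir, "cre_set.bed"),
    expression = file.path(dir, "expression.tsv"),
    nascent = file.path(dir, "nascent.tsv"),
    nascentSamples = file.path(dir, "nascent_samples.tsv"),
    cellMatrix = file.path(dir, "cell_matrix.tsv"),
    truthGenes = file.path(dir, "truth_genes.tsv"),
    truthBins = file.path(dir, "truth_bins.tsv"),
    manifest = file.path(dir, "manifest.yaml"))

  writeLoops(data.frame(loopTable, stringsAsFactors = FALSE), paths$loops)
  .writeBed(peaks, paths$atacPeaks)
  .writeTSV(tss, paths$tss)
  .writeBed(stateRows, paths$states)
  .writeBed(seRows, paths$superEnhancers)
  .writeBed(broadRows, paths$broadPeaks)
  .writeBed(creRows, paths$creSet)
  .writeTSV(data.frame(gene = geneIds, exprM, check.names = FALSE),
            paths$expression)
  .writeTSV(data.frame(gene = geneIds,
                       round(nasM, 6), check.names = FALSE), paths$nascent)
  .writeTSV(data.frame(sample = nasSamples, condition = conds,
                       spikein_factor = p$spikeinFactors),
            paths$nascentSamples)
  .writeTSV(data.frame(gene = geneIds, cellM, check.names = FALSE),
            paths$cellMatrix)
  truthGenes <- data.frame(gene = geneIds, class = classes,
                           chrom = terChrom, promoter_bin = pid,
                           connectivity = unname(conn),
                           stringsAsFactors = FALSE)
  .writeTSV(truthGenes, paths$truthGenes)
  .writeTSV(data.frame(
    bin = c(hubBins, seBins),
    role = c(rep("hub_cre", length(hubBins)),
             rep("super_enhancer", length(seBins)))), paths$truthBins)
  yaml::write_yaml(list(
    seed = p$seed,
    bin_size = p$binSize,
    chromosomes = as.list(chromSizes),
    n_genes = nGenes,
    paths = lapply(paths[names(paths) != "manifest"], basename)),
    paths$manifest)

  invisible(list(params = p, scheme = scheme, paths = paths,
                 truth = list(genes = truthGenes, hubBins = hubBins,
                              sePlantedBins = seBins,
                              promoterBins = structure(pid,
                                                       names = geneIds))))
}

.binIdToBed <- function(binIds, scheme) {
  if (length(binIds) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  parts <- strsplit(binIds, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1)
  start <- as.integer(vapply(parts, `[`, "", 2))
  data.frame(chrom = chrom, start = start,
             end = binEnd(scheme, chrom, start), stringsAsFactors = FALSE)
}

.writeBed <- function(df, path) {
  if (nrow(df)) df <- df[order(df$chrom, df$start), , drop = FALSE]
  fmt <- df
  fmt$start <- format(df$start, scientific = FALSE, trim = TRUE)
  fmt$end <- format(df$end, scientific = FALSE, trim = TRUE)
  .writeTSV(fmt, path, col.names = FALSE)
}

#' Confusion counts of predicted vs planted response classes
#'
#' @param truthGenes Truth table from the bundle (gene, class, ...).
#' @param predicted data.frame(gene, class) from
#'   \code{\link{classifyResponse}}.
#' @return list(confusion = 3x3 table (truth x predicted), perClass =
#'   data.frame(class, tp, fp, fn, recall, precision)).
#' @export
truthEvaluation <- function(truthGenes, predicted) {
  if (!setequal(truthGenes$gene, predicted$gene))
    stop("gene sets of truth and prediction differ")
  lv <- c("memory", "responsive", "nonresponsive")
  tr <- factor(truthGenes$class, levels = lv)
  pr <- factor(predicted$class[match(truthGenes$gene, predicted$gene)],
               levels = lv)
  conf <- table(truth = tr, predicted = pr)
  perClass <- do.call(rbind, lapply(lv, function(cl) {
    tp <- sum(tr == cl & pr == cl)
    fp <- sum(tr != cl & pr == cl)
    fn <- sum(tr == cl & pr != cl)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }))
  list(confusion = conf, perClass = perClass)
}
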