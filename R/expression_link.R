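# Coupling network connectivity to gene expression: weighted gene
# connectivity, percentile binning, the conditional-probability table
# (verified through Bayes' theorem), consensus k-means on z-scored
# expression, and single-cell signature scoring.

#' Gene connectivity from the chromatin network
#'
#' A gene's connectivity is the summed contact count over all distinct edges
#' incident to any bin carrying the gene's promoter (an edge joining two
#' promoter bins of the same gene counts once). Genes whose promoter bin is
#' absent from the network are omitted; a gene on an isolated bin gets 0.
#'
#' @param net A \code{ChromatinNetwork} whose P-class nodes carry gene ids.
#' @return Named numeric vector gene -> connectivity.
#' @export
geneConnectivity <- function(net) {
  g <- net@graph
  genesAttr <- igraph::V(g)$genes
  has <- nzchar(genesAttr) & !is.na(genesAttr)
  if (!any(has)) return(structure(numeric(0), names = character(0)))
  vIdx <- which(has)
  geneLists <- strsplit(genesAttr[vIdx], ",", fixed = TRUE)
  gene2bins <- split(rep(vIdx, lengths(geneLists)), unlist(geneLists))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  out <- vapply(gene2bins, function(bins) {
    inc <- el[, 1] %in% bins | el[, 2] %in% bins
    sum(w[inc])
  }, 0)
  out[order(names(out))]
}

#' Rank-quantile binning of gene connectivity
#'
#' Genes are ranked by connectivity (ties broken by gene id for determinism,
#' with a warning) and split into \code{nBins} equal-rank groups; bin
#' \code{nBins} holds the most connected genes, matching the usual
#' 10th-100th percentile decile construction.
#'
#' @param connectivity Named numeric vector gene -> connectivity.
#' @param nBins Number of quantile bins (default 10).
#' @return Named integer vector gene -> bin index in 1..nBins.
#' @export
percentileBins <- function(connectivity, nBins = 10) {
  if (nBins < 2) stop("nBins must be >= 2")
  n <- length(connectivity)
  if (n < nBins) stop("fewer genes (", n, ") than bins (", nBins, ")")
  ord <- order(connectivity, names(connectivity))
  if (anyDuplicated(connectivity))
    warning("ties in connectivity broken by gene-id order")
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  bins <- as.integer(ceiling(rank * nBins / n))
  structure(bins, names = names(connectivity))
}

#' Probability of above-mean expression per connectivity bin
#'
#' For each connectivity bin, the probability that a gene's transcript count
#' exceeds the population mean (taken over the binned gene set), computed two
#' ways: directly as a conditional frequency and through Bayes' theorem
#' P(count>mean | bin) = P(bin | count>mean) P(count>mean) / P(bin). The two
#' must agree to numerical precision (the decomposition is an identity); the
#' direct value is reported as \code{probability}.
#'
#' @param bins Named integer vector gene -> bin from
#'   \code{\link{percentileBins}}.
#' @param expression Named numeric vector gene -> transcript count, covering
#'   all binned genes.
#' @return list(table = data.frame(bin, n, n_above, probability, p_bayes),
#'   populationMean, pAbove).
#' @export
conditionalExpressionProbability <- function(bins, expression) {
  missing <- setdiff(names(bins), names(expression))
  if (length(missing))
    stop("expression missing for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- expression[names(bins)]
  popMean <- mean(x)
  above <- x > popMean
  pAbove <- mean(above)
  levels <- sort(unique(bins))
  tab <- do.call(rbind, lapply(levels, function(b) {
    sel <- bins == b
    nb <- sum(sel)
    nAbove <- sum(above[sel])
    pDirect <- if (nb > 0) nAbove / nb else NA_real_
    # Bayes: P(bin | above) * P(above) / P(bin)
    pBinGivenAbove <- if (sum(above) > 0) sum(sel & above) / sum(above) else 0
    pBin <- nb / length(bins)
    pBayes <- if (nb > 0) pBinGivenAbove * pAbove / pBin else NA_real_
    data.frame(bin = b, n = nb, n_above = nAbove,
               probability = pDirect, p_bayes = pBayes)
  }))
  ok <- is.na(tab$probability) |
    abs(tab$probability - tab$p_bayes) < 1e-12
  if (!all(ok))
    stop("Bayes decomposition disagrees with direct frequency; ",
         "internal inconsistency")
  list(table = tab, populationMean = popMean, pAbove = pAbove)
}

#' Consensus k-means clustering of row-z-scored expression
#'
#' Rows (genes) are z-scored across samples (zero-variance rows dropped with a
#' warning), then k-means is run \code{repeats} times from distinct seeded
#' initialisations. The consensus partition is the run with the lowest
#' within-cluster sum of squares among runs whose pairwise co-assignments
#' agree with the majority co-assignment matrix on at least half of all gene
#' pairs. Cluster labels are renumbered by increasing cluster mean of the
#' first sample so the labelling is deterministic.
#'
#' @param expr Numeric matrix, genes x samples (rownames = gene ids).
#' @param k Number of clusters (default 3).
#' @param repeats Number of seeded initialisations (default 10).
#' @param seed Integer seed.
#' @return Named integer vector gene -> cluster in 1..k (z-scorable genes
#'   only).
#' @export
consensusKmeansZscores <- function(expr, k = 3, repeats = 10, seed = 1) {
  stopifnot(is.matrix(expr), k >= 1, repeats >= 1)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warning(sum(sds == 0 | is.na(sds)),
            " zero-variance gene row(s) dropped before z-scoring")
    expr <- expr[sds > 0 & !is.na(sds), , drop = FALSE]
  }
  if (k > nrow(expr)) stop("k exceeds the number of usable genes")
  z <- t(scale(t(expr)))
  n <- nrow(z)
  if (k == 1)
    return(structure(rep(1L, n), names = rownames(z)))
  runs <- lapply(seq_len(repeats), function(i) {
    withSeed(stageSeed(seed, paste0("kmeans", i)),
             stats::kmeans(z, centers = k, nstart = 1, iter.max = 100))
  })
  co <- function(cl) outer(cl, cl, "==")
  coMats <- lapply(runs, function(r) co(r$cluster))
  majority <- Reduce("+", coMats) / repeats >= 0.5
  ut <- upper.tri(majority)
  agree <- vapply(coMats, function(m) mean(m[ut] == majority[ut]), 0)
  eligible <- which(agree >= 0.5)
  if (length(eligible) == 0) eligible <- seq_len(repeats)
  wss <- vapply(runs, function(r) r$tot.withinss, 0)
  best <- runs[[eligible[which.min(wss[eligible])]]]
  cl <- best$cluster
  # deterministic labels: order clusters by mean of the first sample
  means <- vapply(split(z[, 1], factor(cl, levels = seq_len(k))), mean, 0)
  newLab <- order(order(means))[cl]
  structure(as.integer(newLab), names = rownames(z))
}

#' Per-cell signature score (median expression of a gene set)
#'
#' @param cellMatrix Numeric matrix, genes x cells.
#' @param geneSet Character vector of signature gene ids; must intersect the
#'   matrix rownames.
#' @return Named numeric vector cell -> median expression over the
#'   intersected gene set.
#' @export
signatureScore <- function(cellMatrix, geneSet) {
  present <- intersect(geneSet, rownames(cellMatrix))
  if (length(present) == 0)
    stop("no signature gene found in the matrix; missing: ",
         paste(utils::head(geneSet, 10), collapse = ", "))
  apply(cellMatrix[present, , drop = FALSE], 2, stats::median)
}

#' Pearson correlation between two per-cell signature scores
#'
#' @param a,b Named numeric score vectors (matched by cell name when named).
#' @return Pearson r over cells with both scores defined.
#' @export
scoreCorrelation <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stats::cor(a, b, use = "complete.obs", method = "pearson")
}

#' Top-n most expressed genes (a condition's signature)
#'
#' Ties at the inclusion boundary are broken by gene-id order, with a warning.
#'
#' @param expr Named numeric vector gene -> expression for one condition.
#' @param n Signature size (default 150).
#' @return Character vector of n gene ids.
#' @export
topNSignature <- function(expr, n = 150) {
  if (n <= 0) stop("n must be positive")
  if (n > length(expr)) stop("n exceeds the number of genes")
  ord <- order(-expr, names(expr))
  if (n < length(expr) && expr[ord[n]] == expr[ord[n + 1]])
    warning("tie at the signature boundary broken by gene-id order")
  names(expr)[ord[seq_len(n)]]
}
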