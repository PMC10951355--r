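# Shared fixtures: all built in code at test time.

# minimal annotation table for hand-built networks
makeAnnotation <- function(bins, chrom = "chr1", binSize = 10000,
                           classes = rep("other", length(bins)),
                           genes = rep("", length(bins)),
                           states = rep("Others", length(bins)),
                           isCRE = rep(FALSE, length(bins))) {
  start <- (seq_along(bins) - 1L) * binSize
  data.frame(bin = bins, chrom = chrom, start = start,
             end = start + binSize, class = classes, genes = genes,
             state = states, isCRE = isCRE, stringsAsFactors = FALSE)
}

# loops data.frame from an edge list over the bins of makeAnnotation()
makeLoops <- function(ann, from, to, weight) {
  i <- match(from, ann$bin)
  j <- match(to, ann$bin)
  data.frame(chrom1 = ann$chrom[i], start1 = ann$start[i],
             end1 = ann$end[i], chrom2 = ann$chrom[j],
             start2 = ann$start[j], end2 = ann$end[j],
             count = as.integer(weight), q = 0.001,
             bin1 = from, bin2 = to, stringsAsFactors = FALSE)
}

# the 4-node toy: b1-b2 w5, b1-b3 w2, b2-b3 w1, b3-b4 w4
toyNetwork <- function(classes = c("P", "E", "E", "P"),
                       genes = c("gA", "", "", "gB")) {
  ann <- makeAnnotation(paste0("b", 1:4), classes = classes, genes = genes)
  loops <- makeLoops(ann,
                     from = c("b1", "b1", "b2", "b3"),
                     to = c("b2", "b3", "b3", "b4"),
                     weight = c(5, 2, 1, 4))
  buildNetwork(loops, ann, 10000, "toy")
}

# random simple weighted network with random P/E/other classes
randomNetwork <- function(n, pEdge = 0.1, seed = 1) {
  withr::with_seed(seed, {
    bins <- sprintf("b%03d", seq_len(n))
    cls <- sample(c("P", "E", "other"), n, replace = TRUE)
    genes <- ifelse(cls == "P", paste0("g", seq_len(n)), "")
    ann <- makeAnnotation(bins, classes = cls, genes = genes)
    pairs <- t(combn(seq_len(n), 2))
    keep <- runif(nrow(pairs)) < pEdge
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0) pairs <- matrix(c(1L, 2L), 1)
    loops <- makeLoops(ann, bins[pairs[, 1]], bins[pairs[, 2]],
                       weight = sample(1:10, nrow(pairs), replace = TRUE))
    buildNetwork(loops, ann, 10000, "random")
  })
}

# brute-force per-edge-scan degree-by-class oracle
oracleDegreeByClass <- function(net, a, b) {
  e <- netEdges(net)
  nodes <- netNodes(net)
  cls <- structure(nodes$class, names = nodes$bin)
  deg <- structure(rep(0L, nrow(nodes)), names = nodes$bin)
  used <- character(0)
  for (i in seq_len(nrow(e))) {
    c1 <- cls[e$bin1[i]]; c2 <- cls[e$bin2[i]]
    if ((c1 == a && c2 == b) || (c1 == b && c2 == a)) {
      deg[e$bin1[i]] <- deg[e$bin1[i]] + 1L
      deg[e$bin2[i]] <- deg[e$bin2[i]] + 1L
      used <- c(used, e$bin1[i], e$bin2[i])
    }
  }
  deg[names(deg) %in% used]
}

# exhaustive CRE-removal null: every k-subset of nodes
oracleExhaustiveP <- function(net, creNodes, tieInclusive = FALSE) {
  nodes <- netNodes(net)$bin
  k <- length(creNodes)
  observed <- averageDegree(removeNodes(net, creNodes))
  sets <- combn(nodes, k, simplify = FALSE)
  null <- vapply(sets, function(s) averageDegree(removeNodes(net, s)), 0)
  if (tieInclusive) mean(null <= observed) else mean(null < observed)
}

# read a synthetic bundle back through the package readers and build the net
buildBundleNetwork <- function(bundle) {
  scheme <- bundle$scheme
  loops <- readLoops(bundle$paths$loops, scheme)
  tss <- readTSS(bundle$paths$tss)
  promoters <- makePromoters(tss, 2500, 100, scheme@chromSizes)
  elements <- classifyElements(readIntervals(bundle$paths$atacPeaks, "peaks"),
                               promoters, 1500)
  ann <- annotateBins(scheme, loops, elements,
                      readIntervals(bundle$paths$creSet, "peaks"))
  ann <- assignStates(ann,
                      readIntervals(bundle$paths$states, "states"),
                      readIntervals(bundle$paths$superEnhancers, "peaks"),
                      readIntervals(bundle$paths$broadPeaks, "peaks"))
  list(net = buildNetwork(loops, ann, scheme@binSize, "bundle"),
       loops = loops, annotation = ann)
}

# GRanges from 0-based half-open coordinates (test-side convenience)
gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}
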