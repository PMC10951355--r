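# Transcriptional-memory gene classification from nascent RNA, per-promoter
# iCD extraction, two-layer community detection, connectivity-threshold
# erosion, and chromatin-state strength.

#' Classify memory / responsive / nonresponsive genes from nascent RNA
#'
#' Values are spike-in normalised, replicates averaged per condition, and two
#' log2 fold changes computed with a pseudocount: the naive response
#' \code{lfc_r = log2((naive_atRA + ps) / (naive_veh + ps))} and the primed
#' amplification \code{lfc_m = log2((primed_atRA + ps) / (naive_atRA + ps))}.
#' A gene is responsive when \code{lfc_r > lfcCut} and memory when
#' additionally \code{lfc_m > lfcCut} (default cut 0.5, the usual log2FC
#' threshold on spike-in normalised FPKM).
#'
#' @param se SummarizedExperiment with colData columns \code{condition}
#'   (levels naive_veh, naive_atRA, primed_atRA) and \code{spikein_factor}.
#' @param lfcCut log2 fold-change cutoff (default 0.5).
#' @param pseudocount Added to both numerator and denominator (default 0.1);
#'   must be positive when any condition mean is zero.
#' @return data.frame(gene, lfc_r, lfc_m, class) with class in
#'   \{memory, responsive, nonresponsive\}.
#' @export
classifyResponse <- function(se, lfcCut = 0.5, pseudocount = 0.1) {
  cond <- SummarizedExperiment::colData(se)$condition
  need <- c("naive_veh", "naive_atRA", "primed_atRA")
  if (is.null(cond) || !all(need %in% cond))
    stop("conditions must include: ", paste(need, collapse = ", "))
  se <- spikeinNormalize(se)
  m <- SummarizedExperiment::assay(se, "normalized")
  cm <- do.call(cbind, lapply(need, function(cc)
    rowMeans(m[, cond == cc, drop = FALSE])))
  colnames(cm) <- need
  if (pseudocount <= 0 && any(cm == 0))
    stop("zero condition means require a positive pseudocount")
  lfcR <- log2((cm[, "naive_atRA"] + pseudocount) /
               (cm[, "naive_veh"] + pseudocount))
  lfcM <- log2((cm[, "primed_atRA"] + pseudocount) /
               (cm[, "naive_atRA"] + pseudocount))
  responsive <- lfcR > lfcCut
  memory <- responsive & (lfcM > lfcCut)
  cls <- ifelse(memory, "memory",
                ifelse(responsive, "responsive", "nonresponsive"))
  data.frame(gene = rownames(m), lfc_r = unname(lfcR), lfc_m = unname(lfcM),
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

# network bins carrying a given gene's promoter
.geneBins <- function(net, gene) {
  g <- net@graph
  geneLists <- strsplit(igraph::V(g)$genes, ",", fixed = TRUE)
  hit <- vapply(geneLists, function(gl) gene %in% gl, TRUE)
  igraph::V(g)$name[hit]
}

#' Extract the interconnected chromatin domain (iCD) of a gene
#'
#' The connected component of the network containing the gene's promoter bin,
#' restricted to the promoter's chromosome, with nodes ordered genomically.
#'
#' @param net A \code{ChromatinNetwork}.
#' @param gene Gene id; its promoter bin must be a network node.
#' @return An \code{\link{ICD-class}} object.
#' @export
extractICD <- function(net, gene) {
  g <- net@graph
  bins <- .geneBins(net, gene)
  if (length(bins) == 0)
    stop("gene ", gene, " has no promoter bin in the network")
  anchor <- bins[1]
  comp <- igraph::components(g)
  member <- comp$membership[anchor]
  inComp <- igraph::V(g)$name[comp$membership == member]
  chrom <- igraph::V(g)$chrom[match(anchor, igraph::V(g)$name)]
  onChrom <- igraph::V(g)$name[igraph::V(g)$chrom == chrom]
  keep <- intersect(inComp, onChrom)
  sub <- igraph::induced_subgraph(g, keep)
  ord <- order(igraph::V(sub)$start)
  new("ICD", gene = gene, graph = sub,
      genomicOrder = igraph::V(sub)$name[ord])
}

#' Extract iCDs for a set of genes
#'
#' Genes whose promoter bin is absent from the network are skipped with a
#' warning listing them.
#'
#' @param net A \code{ChromatinNetwork}.
#' @param genes Character vector of gene ids.
#' @return Named list of \code{ICD} objects.
#' @export
extractICDs <- function(net, genes) {
  ok <- vapply(genes, function(gn) length(.geneBins(net, gn)) > 0, TRUE)
  if (any(!ok))
    warning(sum(!ok), " gene(s) absent from the network: ",
            paste(utils::head(genes[!ok], 5), collapse = ", "))
  out <- lapply(genes[ok], function(gn) extractICD(net, gn))
  names(out) <- genes[ok]
  out
}

#' Two-layer community detection on an iCD
#'
#' Communities are found on a layered graph: layer one is the iCD's weighted
#' edge set (the interaction information), layer two chains genomically
#' adjacent bins (the sequential-order information) with a chain weight equal
#' to the median interaction weight. The coarse partition is seeded Louvain on
#' the combined graph; the fine partition re-runs Louvain inside each coarse
#' community on the interaction layer only, and a bin held in a community
#' solely by the chain is kept with its nearest chain neighbour. Modularity of
#' the coarse partition on the combined graph is reported.
#'
#' @param icd An \code{ICD} with >= 1 node.
#' @param seed Integer seed (Louvain is seeded for determinism).
#' @return list(coarse, fine = named integer memberships, modularity).
#' @export
clusterICD <- function(icd, seed = 1) {
  g <- icd@graph
  n <- igraph::gorder(g)
  nodes <- icd@genomicOrder
  if (n <= 1) {
    one <- structure(rep(1L, n), names = nodes)
    return(list(coarse = one, fine = one, modularity = NA_real_))
  }
  w <- igraph::E(g)$weight
  chainW <- max(1, stats::median(w))
  chain <- as.vector(rbind(nodes[-n], nodes[-1]))
  combined <- igraph::add_edges(g, chain, weight = chainW)
  combined <- igraph::simplify(combined,
                               edge.attr.comb = list(weight = "sum"))
  coarseCl <- withSeed(seed, igraph::cluster_louvain(combined,
                                                     weights = igraph::E(combined)$weight))
  coarse <- structure(as.integer(igraph::membership(coarseCl)),
                      names = igraph::V(combined)$name)
  mod <- igraph::modularity(combined, igraph::membership(coarseCl),
                            weights = igraph::E(combined)$weight)

  # fine level: interaction layer only, within each coarse community
  fine <- integer(length(coarse))
  names(fine) <- names(coarse)
  offset <- 0L
  for (cc in sort(unique(coarse))) {
    members <- names(coarse)[coarse == cc]
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::gsize(sub) == 0) {
      sf <- structure(rep(1L, length(members)),
                      names = igraph::V(sub)$name)
    } else {
      fc <- withSeed(stageSeed(seed, paste0("fine", cc)),
                     igraph::cluster_louvain(sub,
                                             weights = igraph::E(sub)$weight))
      sf <- structure(as.integer(igraph::membership(fc)),
                      names = igraph::V(sub)$name)
    }
    # chain-only nodes (no interaction edge inside the community) stay with
    # their nearest chain neighbour in the same coarse community
    deg <- igraph::degree(sub)
    lone <- names(deg)[deg == 0]
    if (length(lone) && length(members) > 1) {
      pos <- match(members, nodes)
      for (u in lone) {
        others <- setdiff(members, u)
        nb <- others[which.min(abs(match(others, nodes) - match(u, nodes)))]
        sf[u] <- sf[nb]
      }
    }
    fine[members] <- sf[members] + offset
    offset <- offset + max(sf)
  }
  # renumber fine labels consecutively in genomic order of first appearance
  fo <- fine[nodes]
  fine[nodes] <- as.integer(factor(fo, levels = unique(fo)))
  list(coarse = coarse[nodes], fine = fine[nodes], modularity = mod)
}

# survivors of an edge-weight threshold within one iCD: nodes keeping >= 1
# incident edge after removing edges with weight < threshold
.icdSurvivors <- function(icd, threshold) {
  g <- icd@graph
  if (igraph::gsize(g) == 0) return(character(0))
  keep <- igraph::E(g)$weight >= threshold
  gf <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
  igraph::V(gf)$name[igraph::degree(gf) > 0]
}

#' Connectivity percentile thresholds from the global pair-weight multiset
#'
#' Nearest-rank (type 1) quantiles of the contact counts of all pairs, the
#' distribution from which erosion thresholds are drawn.
#'
#' @param weights Numeric vector of all pair connectivities.
#' @param percentiles Percentile points (default 10, 20, ..., 90).
#' @return Named numeric vector of thresholds.
#' @export
connectivityThresholds <- function(weights, percentiles = seq(10, 90, 10)) {
  stats::quantile(weights, percentiles / 100, type = 1, names = TRUE)
}

#' Erosion analysis: survival of regions and promoters under edge filtering
#'
#' At each connectivity-percentile threshold, edges with weight below the
#' threshold are removed from every iCD; a region (bin) survives if it keeps
#' at least one incident edge, and a promoter survives if its own bin does.
#' Fractions are pooled per gene group over the group's unfiltered iCDs
#' (\code{perICD = TRUE} averages the per-iCD fractions instead). Single-node
#' iCDs carry no edges and are excluded with a warning.
#'
#' @param icds Named list of \code{ICD} objects (names = gene ids).
#' @param groups Named character vector gene -> group label (e.g. memory /
#'   responsive).
#' @param globalWeights All pair connectivities in the parent network (the
#'   threshold distribution).
#' @param percentiles Percentile points (default 10..90 by 10).
#' @param perICD Average per-iCD fractions instead of pooling.
#' @return data.frame(group, percentile, threshold, region_fraction,
#'   promoter_fraction).
#' @export
erosionAnalysis <- function(icds, groups, globalWeights,
                            percentiles = seq(10, 90, 10), perICD = FALSE) {
  thr <- connectivityThresholds(globalWeights, percentiles)
  singletons <- vapply(icds, function(ic) igraph::gsize(ic@graph) == 0, TRUE)
  if (any(singletons)) {
    warning(sum(singletons), " single-node iCD(s) excluded from erosion")
    icds <- icds[!singletons]
  }
  glabs <- groups[names(icds)]
  out <- list()
  for (grp in sort(unique(stats::na.omit(glabs)))) {
    sel <- icds[!is.na(glabs) & glabs == grp]
    if (length(sel) == 0) { warning("empty group: ", grp); next }
    allBins <- lapply(sel, icdNodes)
    promoterBin <- vapply(sel, function(ic) {
      gl <- strsplit(igraph::V(ic@graph)$genes, ",", fixed = TRUE)
      hit <- vapply(gl, function(x) ic@gene %in% x, TRUE)
      igraph::V(ic@graph)$name[which(hit)[1]]
    }, "")
    for (i in seq_along(percentiles)) {
      t <- thr[i]
      surv <- lapply(sel, .icdSurvivors, threshold = t)
      if (perICD) {
        rf <- mean(mapply(function(s, a) length(s) / length(a),
                          surv, allBins))
        pf <- mean(mapply(function(s, pb) pb %in% s, surv, promoterBin))
      } else {
        rf <- length(unique(unlist(surv))) /
          length(unique(unlist(allBins)))
        pf <- mean(mapply(function(s, pb) pb %in% s, surv, promoterBin))
      }
      out[[length(out) + 1L]] <- data.frame(
        group = grp, percentile = percentiles[i], threshold = unname(t),
        region_fraction = rf, promoter_fraction = pf,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Chromatin-state strength under connectivity filtering
#'
#' For each gene group and chromatin state: the fraction of that state among
#' bins surviving the threshold filter, divided by its fraction among all of
#' the group's bins. This "filtered / unfiltered" orientation measures
#' resilience (strength > 1 = the state withstands erosion); the reciprocal
#' orientation is emitted alongside. Bins are pooled uniquely per group.
#'
#' @param icds Named list of \code{ICD}s whose nodes carry a \code{state}
#'   attribute (build the network after \code{\link{assignStates}}).
#' @param groups Named character vector gene -> group.
#' @param globalWeights All pair connectivities (threshold distribution).
#' @param percentile Filtering percentile (default 90).
#' @return data.frame(group, state, frac_unfiltered, frac_filtered, strength,
#'   strength_reciprocal).
#' @export
stateStrength <- function(icds, groups, globalWeights, percentile = 90) {
  thr <- connectivityThresholds(globalWeights, percentile)[1]
  glabs <- groups[names(icds)]
  out <- list()
  for (grp in sort(unique(stats::na.omit(glabs)))) {
    sel <- icds[!is.na(glabs) & glabs == grp]
    binState <- do.call(c, unname(lapply(sel, function(ic) {
      structure(igraph::V(ic@graph)$state, names = igraph::V(ic@graph)$name)
    })))
    binState <- binState[!duplicated(names(binState))]
    survivors <- unique(unlist(lapply(sel, .icdSurvivors, threshold = thr)))
    if (length(survivors) == 0) {
      warning("no surviving bins in group ", grp,
              " at percentile ", percentile, "; strengths undefined")
      next
    }
    states <- sort(unique(binState))
    for (st in states) {
      fu <- mean(binState == st)
      ff <- mean(binState[survivors] == st)
      out[[length(out) + 1L]] <- data.frame(
        group = grp, state = st, frac_unfiltered = fu, frac_filtered = ff,
        strength = ff / fu,
        strength_reciprocal = if (ff > 0) fu / ff else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
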