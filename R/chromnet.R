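# The bin-level chromatin interaction network and its degree statistics.

#' Build a chromatin interaction network from significant loops
#'
#' Nodes are the bins appearing as loop anchors; an undirected edge joins two
#' bins when they form a significant loop, weighted by the pair's contact
#' count (its connectivity). The graph is simple: duplicate pair rows are
#' merged by summing counts.
#'
#' @param loops Loop data.frame from \code{\link{readLoops}}.
#' @param annotation Bin annotation from \code{\link{annotateBins}} (and
#'   optionally \code{\link{assignStates}}); must cover every loop anchor.
#' @param binSize Bin width in bp (metadata).
#' @param sample Sample label (metadata).
#' @return A \code{\link{ChromatinNetwork-class}} object.
#' @export
buildNetwork <- function(loops, annotation, binSize, sample = "sample") {
  anchors <- unique(c(loops$bin1, loops$bin2))
  missing <- setdiff(anchors, annotation$bin)
  if (length(missing))
    stop("loop anchor bin(s) missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  nodes <- annotation[order(annotation$chrom, annotation$start), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = loops$bin1, to = loops$bin2,
                   weight = loops$count, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes$bin, chrom = nodes$chrom,
                          start = nodes$start, end = nodes$end,
                          class = nodes$class, genes = nodes$genes,
                          state = nodes$state, isCRE = nodes$isCRE,
                          stringsAsFactors = FALSE))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(weight = "sum"))
  new("ChromatinNetwork", graph = g, binSize = as.integer(binSize),
      sample = sample)
}

#' Average network degree
#'
#' \code{2|E| / |N|}; isolated nodes count in \code{|N|}.
#'
#' @param net A \code{ChromatinNetwork} (or bare igraph).
#' @return The average unweighted degree.
#' @export
averageDegree <- function(net) {
  g <- if (is(net, "ChromatinNetwork")) net@graph else net
  n <- igraph::gorder(g)
  if (n == 0) stop("average degree undefined on an empty network")
  2 * igraph::gsize(g) / n
}

#' Node degrees within each contact-class subnetwork
#'
#' For each contact class (P-P, E-E, P-E) the subnetwork keeps only edges
#' whose endpoint classes match the pair; the reported degree of a
#' participating node is its unweighted edge count within that subnetwork.
#' Nodes of class \code{other} never enter a class subnetwork.
#'
#' @param net A \code{ChromatinNetwork}.
#' @return list(PP, EE, PE = named integer degree vectors;
#'   summary = data.frame(class, n_nodes, n_edges, mean, median, max)).
#' @export
degreeByClass <- function(net) {
  g <- net@graph
  cls <- igraph::V(g)$class
  names(cls) <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  c1 <- cls[el[, 1]]
  c2 <- cls[el[, 2]]
  pick <- function(a, b) {
    sel <- (c1 == a & c2 == b) | (c1 == b & c2 == a)
    if (!any(sel)) return(structure(integer(0), names = character(0)))
    tab <- table(c(el[sel, 1], el[sel, 2]))
    structure(as.integer(tab), names = names(tab))
  }
  res <- list(PP = pick("P", "P"), EE = pick("E", "E"), PE = pick("P", "E"))
  res$summary <- do.call(rbind, lapply(names(res)[1:3], function(k) {
    d <- res[[k]]
    data.frame(class = k, n_nodes = length(d),
               n_edges = sum(d) / 2,
               mean = if (length(d)) mean(d) else NA_real_,
               median = if (length(d)) stats::median(d) else NA_real_,
               max = if (length(d)) max(d) else NA_integer_)
  }))
  res
}

#' Compare degree distributions across samples
#'
#' Kruskal-Wallis across all groups plus pairwise two-sided Mann-Whitney U
#' tests, with the usual tie correction and asymptotic p-values.
#'
#' @param groups Named list of >= 2 numeric degree vectors.
#' @return list(kruskal = list(H, p), pairwise = data.frame(group1, group2,
#'   U, p)).
#' @export
compareDegreeDistributions <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups of degrees")
  if (any(vapply(groups, length, 0L) < 1))
    stop("every group needs at least one observation")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  cmb <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, apply(cmb, 2, function(pair) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[pair[1]]],
                                              groups[[pair[2]]],
                                              exact = FALSE, correct = TRUE))
    data.frame(group1 = pair[1], group2 = pair[2],
               U = unname(wt$statistic), p = wt$p.value)
  }))
  list(kruskal = list(H = unname(kw$statistic), p = kw$p.value),
       pairwise = pw)
}

#' Loop-participation count per bin (hubs)
#'
#' Counts, for every bin, the number of distinct significant pairs it appears
#' in (duplicates should have been merged upstream by \code{readLoops}).
#'
#' @param loops Loop data.frame.
#' @return Named integer vector, decreasing; bins in many pairs are hubs.
#' @export
hubCounts <- function(loops) {
  if (nrow(loops) == 0) return(structure(integer(0), names = character(0)))
  tab <- table(c(loops$bin1, loops$bin2))
  out <- structure(as.integer(tab), names = names(tab))
  out[order(-out, names(out))]
}
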