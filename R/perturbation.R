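# CRE-removal permutation test: is the average degree after deleting
# CRE-overlapping nodes lower than after deleting equally many random nodes?

#' Delete nodes (and their incident edges) from a network
#'
#' Surviving nodes left isolated by the deletion are retained; they still
#' count in the average degree.
#'
#' @param net A \code{ChromatinNetwork}.
#' @param nodes Bin ids to remove (must all be network nodes).
#' @return A new \code{ChromatinNetwork}.
#' @export
removeNodes <- function(net, nodes) {
  g <- net@graph
  unknown <- setdiff(nodes, igraph::V(g)$name)
  if (length(unknown))
    stop("node(s) not in network: ", paste(utils::head(unknown, 5),
                                           collapse = ", "))
  if (length(nodes) >= igraph::gorder(g))
    stop("cannot remove every node: average degree would be undefined")
  new("ChromatinNetwork",
      graph = igraph::delete_vertices(g, nodes),
      binSize = net@binSize, sample = net@sample)
}

#' Permutation test for the impact of CRE-node removal on average degree
#'
#' The observed statistic is the average degree of the network after deleting
#' the CRE-overlapping nodes. Each of \code{nPerm} permutations deletes the
#' same number of nodes drawn uniformly without replacement from all network
#' nodes (the CRE nodes themselves stay in the pool) and records the resulting
#' average degree, always computed over the remaining nodes. The empirical
#' p-value is the fraction of permutations whose average degree falls strictly
#' below the observed one; \code{tieInclusive = TRUE} switches to the
#' conservative \code{<=} count. No pseudo-count is added: p = 0 is reported
#' as such (it means p < 1/nPerm).
#'
#' @param net A \code{ChromatinNetwork}.
#' @param creNodes Bin ids overlapping the CREs of interest; non-empty strict
#'   subset of the nodes.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed; with the same seed the result is reproducible
#'   bit for bit.
#' @param tieInclusive Count null values equal to the observed one?
#' @return list of class \code{PermutationResult}: observed, nullValues,
#'   nPerm, pValue, seed, removedCount.
#' @export
creRemovalTest <- function(net, creNodes, nPerm = 1000, seed = 1,
                           tieInclusive = FALSE) {
  g <- net@graph
  nodes <- igraph::V(g)$name
  if (length(creNodes) == 0) stop("creNodes must be non-empty")
  unknown <- setdiff(creNodes, nodes)
  if (length(unknown))
    stop("CRE node(s) not in network: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  creNodes <- unique(creNodes)
  k <- length(creNodes)
  n <- length(nodes)
  if (k >= n) stop("CRE nodes must be a strict subset of the network nodes")
  if (nPerm < 1) stop("nPerm must be >= 1")

  el <- igraph::as_edgelist(g, names = FALSE)
  idx <- match(creNodes, nodes)
  avgAfter <- function(removedIdx) {
    inSet <- logical(n)
    inSet[removedIdx] <- TRUE
    eSurv <- sum(!(inSet[el[, 1]] | inSet[el[, 2]]))
    2 * eSurv / (n - length(removedIdx))
  }
  observed <- avgAfter(idx)
  nullValues <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    avgAfter(sample.int(n, k))
  }, 0))
  hits <- if (tieInclusive) sum(nullValues <= observed)
          else sum(nullValues < observed)
  p <- hits / nPerm
  if (p == 0)
    message("empirical p = 0: report as p < ", format(1 / nPerm))
  structure(list(observed = observed, nullValues = nullValues,
                 nPerm = as.integer(nPerm), pValue = p,
                 seed = as.integer(seed), removedCount = k),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat("CRE-removal permutation test\n",
      "  nodes removed : ", x$removedCount, "\n",
      "  observed avg degree after removal: ", format(x$observed), "\n",
      "  permutations  : ", x$nPerm, "\n",
      "  empirical p   : ", format(x$pValue),
      if (x$pValue == 0) paste0(" (< ", format(1 / x$nPerm), ")") else "",
      "\n", sep = "")
  invisible(x)
}
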