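#' @import methods
NULL

#' BinScheme: fixed-size genomic binning
#'
#' Tiles each chromosome into half-open bins \code{[k*binSize, (k+1)*binSize)}
#' (0-based coordinates, BED convention), clipped at the chromosome end. Bins
#' are the node unit of the chromatin interaction network; a bin is identified
#' by the string \code{"chrom:start"}.
#'
#' @slot binSize Bin width in bp (positive integer; the study uses 10 and
#'   25 kb resolutions).
#' @slot chromSizes Named numeric vector of chromosome lengths in bp.
#'
#' @examples
#' scheme <- BinScheme(10000, c(chr1 = 5e6))
#' binStart(scheme, "chr1", 12345)   # 10000
#' @export
setClass("BinScheme",
         representation(binSize = "integer", chromSizes = "numeric"))

setValidity("BinScheme", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize <= 0L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (length(object@chromSizes) == 0L ||
      is.null(names(object@chromSizes)) ||
      any(!nzchar(names(object@chromSizes))))
    msg <- c(msg, "chromSizes must be a non-empty named vector")
  if (any(object@chromSizes <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' @param binSize Bin width in bp.
#' @param chromSizes Named vector of chromosome lengths.
#' @rdname BinScheme-class
#' @export
BinScheme <- function(binSize, chromSizes) {
  new("BinScheme", binSize = as.integer(binSize),
      chromSizes = structure(as.numeric(chromSizes),
                             names = names(chromSizes)))
}

#' @describeIn BinScheme-class Start (0-based) of the bin containing a position.
#' @param scheme A \code{BinScheme}.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s).
#' @export
binStart <- function(scheme, chrom, pos) {
  stopifnot(all(chrom %in% names(scheme@chromSizes)))
  as.integer(floor(pos / scheme@binSize) * scheme@binSize)
}

#' @describeIn BinScheme-class End (exclusive) of the bin starting at
#'   \code{start}, clipped to the chromosome end.
#' @param start 0-based bin start(s).
#' @export
binEnd <- function(scheme, chrom, start) {
  as.integer(pmin(start + scheme@binSize, scheme@chromSizes[chrom]))
}

setMethod("show", "BinScheme", function(object) {
  cat("BinScheme:", object@binSize, "bp bins over",
      length(object@chromSizes), "chromosome(s)\n")
})

#' ChromatinNetwork: bin-level chromatin interaction network
#'
#' An undirected simple graph whose nodes are genomic bins participating in at
#' least one significant HiChIP loop and whose edge weights are contact counts
#' ("connectivity" of the pair). Node annotations (element class P/E/other,
#' linked genes, chromatin state, CRE overlap) are stored as igraph vertex
#' attributes.
#'
#' @slot graph An \code{igraph} object (undirected, simple, weighted).
#' @slot binSize Bin width in bp of the underlying scheme.
#' @slot sample Free-text sample label.
#' @export
setClass("ChromatinNetwork",
         representation(graph = "ANY", binSize = "integer",
                        sample = "character"))

setValidity("ChromatinNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::gsize(g) > 0) {
    if (!igraph::is_simple(g))
      msg <- c(msg, "graph must be simple (no self-loops/multi-edges)")
    w <- igraph::E(g)$weight
    if (is.null(w) || any(w < 1))
      msg <- c(msg, "all edge weights must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChromatinNetwork", function(object) {
  g <- object@graph
  cat("ChromatinNetwork (", object@sample, "): ",
      igraph::gorder(g), " bins, ", igraph::gsize(g), " interactions, ",
      object@binSize, " bp bins\n", sep = "")
  if (igraph::gorder(g) > 0) {
    cls <- table(factor(igraph::V(g)$class, levels = c("P", "E", "other")))
    cat("  node classes: P=", cls[["P"]], " E=", cls[["E"]],
        " other=", cls[["other"]], "\n", sep = "")
  }
})

#' @describeIn ChromatinNetwork-class The underlying igraph object.
#' @param net A \code{ChromatinNetwork}.
#' @export
netGraph <- function(net) net@graph

#' @describeIn ChromatinNetwork-class Node table (bin, chrom, start, end,
#'   class, genes, state, isCRE) as a data.frame.
#' @export
netNodes <- function(net) {
  g <- net@graph
  data.frame(bin = igraph::V(g)$name,
             chrom = igraph::V(g)$chrom,
             start = igraph::V(g)$start,
             end = igraph::V(g)$end,
             class = igraph::V(g)$class,
             genes = igraph::V(g)$genes,
             state = igraph::V(g)$state,
             isCRE = igraph::V(g)$isCRE,
             stringsAsFactors = FALSE)
}

#' @describeIn ChromatinNetwork-class Edge table (bin1, bin2, weight).
#' @export
netEdges <- function(net) {
  g <- net@graph
  if (igraph::gsize(g) == 0)
    return(data.frame(bin1 = character(), bin2 = character(),
                      weight = numeric()))
  ends <- igraph::as_edgelist(g, names = TRUE)
  data.frame(bin1 = ends[, 1], bin2 = ends[, 2],
             weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
}

#' ICD: interconnected chromatin domain of one promoter
#'
#' The connected component of the chromatin network containing a gene's
#' promoter bin, restricted to the promoter's chromosome, with nodes kept in
#' genomic order (the second information layer used when clustering).
#'
#' @slot gene Gene identifier of the anchoring promoter.
#' @slot graph igraph subgraph (nodes carry the network annotations).
#' @slot genomicOrder Character vector of node names sorted by coordinate.
#' @export
setClass("ICD",
         representation(gene = "character", graph = "ANY",
                        genomicOrder = "character"))

setValidity("ICD", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::gorder(g) > 0 && !setequal(igraph::V(g)$name,
                                         object@genomicOrder))
    msg <- c(msg, "genomicOrder must list exactly the graph's nodes")
  if (igraph::gorder(g) > 1 && igraph::count_components(g) != 1)
    msg <- c(msg, "iCD subgraph must be connected")
  if (igraph::gorder(g) > 0 &&
      length(unique(igraph::V(g)$chrom)) != 1L)
    msg <- c(msg, "iCD must lie on a single chromosome")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ICD", function(object) {
  cat("ICD for gene ", object@gene, ": ", igraph::gorder(object@graph),
      " bins, ", igraph::gsize(object@graph), " interactions\n", sep = "")
})

#' @describeIn ICD-class Node names in genomic order.
#' @param icd An \code{ICD}.
#' @export
icdNodes <- function(icd) icd@genomicOrder

#' @describeIn ICD-class The anchoring gene id.
#' @export
icdGene <- function(icd) icd@gene

#' @describeIn ICD-class The igraph subgraph.
#' @export
icdGraph <- function(icd) icd@graph
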