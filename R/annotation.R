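# Promoter/element definitions and bin annotation.
#
# Promoters span 2.5 kb upstream to 100 bp downstream of the TSS by default;
# regulatory elements (enhancers) are ATAC peaks that stay clear of any
# promoter within a 1.5 kb window. Bins inherit class P > E > other, the genes
# whose promoters they overlap, and a single chromatin state picked by the
# 11-level precedence hierarchy.

#' Build promoter intervals around TSSs
#'
#' For a + strand gene the promoter covers \code{[tss - up, tss + down)}
#' (0-based half-open); for a - strand gene the window is mirrored:
#' \code{[tss - down, tss + up)}. Intervals are clipped at position 0 and, when
#' chromosome sizes are supplied, at the chromosome end.
#'
#' @param tss data.frame(gene, chrom, tss, strand) as from \code{\link{readTSS}}.
#' @param up Upstream extent in bp (default 2500).
#' @param down Downstream extent in bp (default 100).
#' @param chromSizes Optional named vector of chromosome lengths for clipping.
#' @return A \code{GRanges} named by gene id, one range per gene.
#' @export
makePromoters <- function(tss, up = 2500, down = 100, chromSizes = NULL) {
  stopifnot(up >= 0, down >= 0)
  if (up + down <= 0)
    stop("degenerate promoter window: up + down must be > 0")
  plus <- tss$strand == "+"
  start0 <- ifelse(plus, tss$tss - up, tss$tss - down)
  end0 <- ifelse(plus, tss$tss + down, tss$tss + up)
  start0 <- pmax(start0, 0)
  if (!is.null(chromSizes))
    end0 <- pmin(end0, chromSizes[tss$chrom])
  if (any(start0 >= end0))
    stop("promoter clipped to an empty interval for gene ",
         tss$gene[which(start0 >= end0)[1]])
  gr <- .bedToGRanges(tss$chrom, start0, end0, tss$strand)
  names(gr) <- tss$gene
  gr
}

#' Split ATAC peaks into promoter-overlapping and enhancer elements
#'
#' A peak is an enhancer iff, after symmetric extension by \code{window} bp,
#' it still overlaps no promoter; peaks failing the test are absorbed into the
#' promoter class. With \code{window = 0} a peak exactly abutting a promoter
#' (half-open intervals) is an enhancer.
#'
#' @param peaks \code{GRanges} of ATAC peaks.
#' @param promoters \code{GRanges} named by gene, from
#'   \code{\link{makePromoters}}.
#' @param window Exclusion window in bp (default 1500).
#' @return list(promoters = the input promoters, enhancers = GRanges subset of
#'   peaks, promoterPeaks = peaks absorbed into the promoter class).
#' @export
classifyElements <- function(peaks, promoters, window = 1500) {
  stopifnot(window >= 0)
  if (length(peaks) == 0)
    return(list(promoters = promoters, enhancers = peaks,
                promoterPeaks = peaks))
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(pmax(GenomicRanges::start(peaks) - window, 1L),
                     GenomicRanges::end(peaks) + window))
  hit <- IRanges::overlapsAny(ext, promoters, ignore.strand = TRUE)
  list(promoters = promoters,
       enhancers = peaks[!hit],
       promoterPeaks = peaks[hit])
}

#' Annotate the bins participating in loops
#'
#' Only bins that appear as an anchor of at least one loop are annotated.
#' Class follows the precedence P > E > other: a bin is P when it overlaps any
#' promoter (its \code{genes} field lists every such gene), otherwise E when
#' it overlaps an enhancer element, otherwise other. \code{isCRE} marks any
#' overlap with a set of CREs of interest (e.g. condition-enriched ATAC
#' peaks).
#'
#' @param scheme \code{\link{BinScheme}} the loops are aligned to.
#' @param loops Loop data.frame from \code{\link{readLoops}}.
#' @param elements list(promoters, enhancers) from
#'   \code{\link{classifyElements}}.
#' @param creSet Optional \code{GRanges} of CREs of interest.
#' @return data.frame(bin, chrom, start, end, class, genes, state, isCRE);
#'   \code{genes} is a comma-separated sorted list, \code{state} is NA until
#'   \code{\link{assignStates}} is applied.
#' @export
annotateBins <- function(scheme, loops, elements,
                         creSet = GenomicRanges::GRanges()) {
  bins <- unique(data.frame(
    bin = c(loops$bin1, loops$bin2),
    chrom = c(loops$chrom1, loops$chrom2),
    start = c(loops$start1, loops$start2),
    end = c(loops$end1, loops$end2),
    stringsAsFactors = FALSE))
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  rownames(bins) <- NULL
  if (nrow(bins) == 0)
    return(data.frame(bin = character(), chrom = character(),
                      start = integer(), end = integer(),
                      class = character(), genes = character(),
                      state = character(), isCRE = logical()))
  gr <- .bedToGRanges(bins$chrom, bins$start, bins$end)

  genes <- character(nrow(bins))
  if (length(elements$promoters)) {
    ov <- GenomicRanges::findOverlaps(gr, elements$promoters,
                                      ignore.strand = TRUE)
    gl <- split(names(elements$promoters)[S4Vectors::subjectHits(ov)],
                factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(bins))))
    genes <- vapply(gl, function(g) paste(sort(unique(g)), collapse = ","), "")
  }
  isE <- if (length(elements$enhancers))
    IRanges::overlapsAny(gr, elements$enhancers, ignore.strand = TRUE)
  else rep(FALSE, nrow(bins))
  cls <- ifelse(nzchar(genes), "P", ifelse(isE, "E", "other"))
  isCRE <- if (length(creSet))
    IRanges::overlapsAny(gr, creSet, ignore.strand = TRUE)
  else rep(FALSE, nrow(bins))

  data.frame(bin = bins$bin, chrom = bins$chrom,
             start = as.integer(bins$start), end = as.integer(bins$end),
             class = cls, genes = genes,
             state = NA_character_, isCRE = isCRE,
             stringsAsFactors = FALSE)
}

#' Assign one chromatin state per bin by the precedence hierarchy
#'
#' Each bin receives the highest-ranked state among all overlapping state
#' intervals, with SuperEnhancer and BroadPeak tracks supplied separately at
#' the top of the hierarchy; bins overlapping nothing get \code{Others}. A tie
#' among intervals of the same rank is resolved by largest overlap, then by
#' position. The operation is idempotent (states are recomputed from the
#' interval inputs).
#'
#' @param annotation Bin annotation from \code{\link{annotateBins}}.
#' @param states \code{GRanges} with a \code{state} column (levels 3-11 of the
#'   hierarchy, though any vocabulary label is accepted).
#' @param superEnhancers \code{GRanges} of super-enhancer intervals (rank 1).
#' @param broadPeaks \code{GRanges} of broad promoter-mark domains (rank 2).
#' @return The annotation with the \code{state} column filled.
#' @export
assignStates <- function(annotation, states,
                         superEnhancers = GenomicRanges::GRanges(),
                         broadPeaks = GenomicRanges::GRanges()) {
  lv <- stateLevels()
  allGr <- c(
    if (length(superEnhancers)) {
      g <- superEnhancers; S4Vectors::mcols(g) <- NULL
      S4Vectors::mcols(g)$state <- "SuperEnhancer"; list(g)
    },
    if (length(broadPeaks)) {
      g <- broadPeaks; S4Vectors::mcols(g) <- NULL
      S4Vectors::mcols(g)$state <- "BroadPeak"; list(g)
    },
    if (length(states)) list(states[, "state"]))
  annotation$state <- "Others"
  if (is.null(allGr) || length(allGr) == 0 || nrow(annotation) == 0)
    return(annotation)
  stateGr <- do.call(c, allGr)
  bad <- !(S4Vectors::mcols(stateGr)$state %in% lv)
  if (any(bad)) stop("state label outside the 11-level vocabulary: ",
                     paste(unique(S4Vectors::mcols(stateGr)$state[bad]),
                           collapse = ", "))
  binGr <- .bedToGRanges(annotation$chrom, annotation$start, annotation$end)
  ov <- GenomicRanges::findOverlaps(binGr, stateGr, ignore.strand = TRUE)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    rank <- match(S4Vectors::mcols(stateGr)$state[sh], lv)
    wid <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(binGr)[qh], IRanges::ranges(stateGr)[sh]))
    # per bin: min rank, ties by largest overlap, then first interval
    ord <- order(qh, rank, -wid, sh)
    keep <- ord[!duplicated(qh[ord])]
    annotation$state[qh[keep]] <-
      S4Vectors::mcols(stateGr)$state[sh[keep]]
  }
  annotation
}

#' H3K4me3 (or other mark) peak breadth at each TSS
#'
#' Reports, per gene, the width of the peak covering the TSS base; \code{NA}
#' when no peak covers it; the widest peak when several do.
#'
#' @param peaks \code{GRanges} of called peaks.
#' @param tss data.frame(gene, chrom, tss, strand).
#' @return Named numeric vector of breadths in bp (NA = no covering peak).
#' @export
breadthAtTSS <- function(peaks, tss) {
  out <- structure(rep(NA_real_, nrow(tss)), names = tss$gene)
  if (length(peaks) == 0 || nrow(tss) == 0) return(out)
  pts <- .bedToGRanges(tss$chrom, tss$tss, tss$tss + 1L)
  ov <- GenomicRanges::findOverlaps(pts, peaks, ignore.strand = TRUE)
  if (length(ov)) {
    w <- IRanges::width(peaks)[S4Vectors::subjectHits(ov)]
    best <- vapply(split(w, S4Vectors::queryHits(ov)), max, 0)
    out[as.integer(names(best))] <- best
  }
  out
}
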