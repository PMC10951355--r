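# Readers and writers for the plain-text formats the pipeline consumes.
# Coordinates in files are 0-based half-open (BED convention) throughout;
# in-memory GRanges follow the usual 1-based closed Bioconductor convention
# and conversion happens only at the I/O boundary.

#' Ordered chromatin-state vocabulary
#'
#' The 11-level annotation hierarchy used to assign a single state per network
#' bin, from highest to lowest precedence.
#'
#' @return Character vector of the 11 state labels in precedence order.
#' @export
stateLevels <- function() {
  c("SuperEnhancer", "BroadPeak", "ActivePromoter", "ActiveEnhancer",
    "WeakPromoter", "WeakEnhancer", "InactivePoisedPromoter", "Insulator",
    "PolycombRepressed", "Heterochromatin", "Others")
}

#' Default alias table for chromatin-state labels
#'
#' Maps common segmentation labels (ChromHMM-style) onto the 11-level
#' vocabulary. Labels absent from the table are mapped to \code{Others} with a
#' warning at read time.
#'
#' @return Named character vector: input label -> vocabulary label.
#' @export
defaultStateAliases <- function() {
  lv <- stateLevels()
  c(structure(lv, names = lv),
    "Super Enhancer"           = "SuperEnhancer",
    "Super-Enhancer"           = "SuperEnhancer",
    "Broad Peak"               = "BroadPeak",
    "Active Promoter"          = "ActivePromoter",
    "Active Enhancer"          = "ActiveEnhancer",
    "Strong_Enhancer"          = "ActiveEnhancer",
    "Weak Promoter"            = "WeakPromoter",
    "Weak Enhancer"            = "WeakEnhancer",
    "Poised_Promoter"          = "InactivePoisedPromoter",
    "Inactive/poised Promoter" = "InactivePoisedPromoter",
    "CTCF"                     = "Insulator",
    "Polycomb_Repressed"       = "PolycombRepressed",
    "Polycomb-repressed"       = "PolycombRepressed",
    "Repressed"                = "PolycombRepressed",
    "Heterochrom"              = "Heterochromatin")
}

.readTabLines <- function(path, minCols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "#", blank.lines.skip = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stop(e)
    })
  if (nrow(raw) == 0) return(raw)
  if (ncol(raw) < minCols)
    stop(what, ": expected >= ", minCols, " tab-separated columns, found ",
         ncol(raw))
  raw
}

# coerce a character column to numeric, reporting the 1-based data line of the
# first malformed value
.numCol <- function(x, colName, lineOffset = 0L) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("malformed numeric value '", x[bad[1]], "' in column ", colName,
         " at line ", bad[1] + lineOffset)
  out
}

#' Read significant loops from a BEDPE-like table
#'
#' Expects tab-separated columns chrom1, start1, end1, chrom2, start2, end2,
#' contact_count, q_value (a header line is auto-detected). Records are
#' filtered to \code{q_value <= qThreshold} (default 0.01, the usual FDR cut
#' for significant HiChIP loops), validated against the bin scheme, ordered so
#' that bin1 <= bin2, and duplicate pairs are merged by summing contact counts
#' (keeping the smaller q-value).
#'
#' @param path Path to the BEDPE-like file.
#' @param scheme A \code{\link{BinScheme}}; every loop anchor must be a scheme
#'   bin.
#' @param qThreshold Significance cutoff on the q-value column.
#' @param allowTrans Keep inter-chromosomal pairs? Default \code{FALSE}
#'   (rejected with an error), as the loops analysed here are cis contacts.
#' @return A data.frame with columns chrom1, start1, end1, chrom2, start2,
#'   end2, count, q, bin1, bin2 (bin ids \code{"chrom:start"}); zero rows for
#'   an empty file.
#' @export
readLoops <- function(path, scheme, qThreshold = 0.01, allowTrans = FALSE) {
  stopifnot(is(scheme, "BinScheme"))
  if (!file.exists(path)) stop("file not found: ", path)
  emptyLoops <- data.frame(chrom1 = character(), start1 = integer(),
                           end1 = integer(), chrom2 = character(),
                           start2 = integer(), end2 = integer(),
                           count = integer(), q = numeric(),
                           bin1 = character(), bin2 = character())
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(emptyLoops)
  hasHeader <- nzchar(first) &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = hasHeader,
                      colClasses = "character", quote = "",
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stop(e)
    })
  if (nrow(raw) == 0) return(emptyLoops)
  if (ncol(raw) < 8)
    stop("loop file needs >= 8 columns ",
         "(chrom1,start1,end1,chrom2,start2,end2,contact_count,q_value)")
  off <- if (hasHeader) 1L else 0L
  df <- data.frame(
    chrom1 = raw[[1]],
    start1 = .numCol(raw[[2]], "start1", off),
    end1   = .numCol(raw[[3]], "end1", off),
    chrom2 = raw[[4]],
    start2 = .numCol(raw[[5]], "start2", off),
    end2   = .numCol(raw[[6]], "end2", off),
    count  = .numCol(raw[[7]], "contact_count", off),
    q      = .numCol(raw[[8]], "q_value", off),
    stringsAsFactors = FALSE)

  validateBinAnchor <- function(chrom, start, end, side) {
    unknown <- !(chrom %in% names(scheme@chromSizes))
    if (any(unknown))
      stop("unknown chromosome '", chrom[which(unknown)[1]],
           "' in loop anchor ", side)
    misaligned <- (start %% scheme@binSize != 0) |
      (end != binEnd(scheme, chrom, start)) | (start < 0)
    if (any(misaligned))
      stop("loop anchor ", side, " not aligned to the ", scheme@binSize,
           " bp bin scheme at data line ", which(misaligned)[1])
  }
  validateBinAnchor(df$chrom1, df$start1, df$end1, "1")
  validateBinAnchor(df$chrom2, df$start2, df$end2, "2")
  if (any(df$count < 1 | df$count != round(df$count)))
    stop("contact_count must be a positive integer (data line ",
         which(df$count < 1 | df$count != round(df$count))[1], ")")
  if (any(df$q < 0 | df$q > 1))
    stop("q_value outside [0, 1] (data line ",
         which(df$q < 0 | df$q > 1)[1], ")")
  if (!allowTrans && any(df$chrom1 != df$chrom2))
    stop("inter-chromosomal pair at data line ",
         which(df$chrom1 != df$chrom2)[1],
         " (set allowTrans = TRUE to keep trans pairs)")
  self <- df$chrom1 == df$chrom2 & df$start1 == df$start2
  if (any(self))
    stop("self-loop (identical anchors) at data line ", which(self)[1])

  df <- df[df$q <= qThreshold, , drop = FALSE]
  if (nrow(df) == 0) return(emptyLoops)

  # normalise anchor order: (chrom, start) lexicographic
  flip <- (df$chrom1 > df$chrom2) |
    (df$chrom1 == df$chrom2 & df$start1 > df$start2)
  if (any(flip)) {
    tmp <- df[flip, c("chrom1", "start1", "end1")]
    df[flip, c("chrom1", "start1", "end1")] <-
      df[flip, c("chrom2", "start2", "end2")]
    df[flip, c("chrom2", "start2", "end2")] <- tmp
  }
  df$bin1 <- .binId(df$chrom1, df$start1)
  df$bin2 <- .binId(df$chrom2, df$start2)

  # merge duplicate pairs: sum counts, keep the smaller q
  key <- paste(df$bin1, df$bin2)
  if (anyDuplicated(key)) {
    agg <- lapply(split(seq_len(nrow(df)), key), function(i) {
      r <- df[i[1], , drop = FALSE]
      r$count <- sum(df$count[i])
      r$q <- min(df$q[i])
      r
    })
    df <- do.call(rbind, agg)
  }
  df <- df[order(df$chrom1, df$start1, df$chrom2, df$start2), , drop = FALSE]
  rownames(df) <- NULL
  df$count <- as.integer(df$count)
  df[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
         "count", "q", "bin1", "bin2")]
}

#' Write loops as a BEDPE-like table
#'
#' Emits the 8 canonical columns, tab-separated with a header, such that
#' \code{readLoops(writeLoops(x))} reproduces \code{x} exactly.
#'
#' @param loops Loop data.frame as returned by \code{\link{readLoops}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeLoops <- function(loops, path) {
  out <- data.frame(chrom1 = loops$chrom1,
                    start1 = format(loops$start1, scientific = FALSE, trim = TRUE),
                    end1 = format(loops$end1, scientific = FALSE, trim = TRUE),
                    chrom2 = loops$chrom2,
                    start2 = format(loops$start2, scientific = FALSE, trim = TRUE),
                    end2 = format(loops$end2, scientific = FALSE, trim = TRUE),
                    contact_count = loops$count,
                    q_value = vapply(loops$q, function(z) sprintf("%.15g", z), ""))
  .writeTSV(out, path)
}

#' Read a BED file of peaks or chromatin-state segments
#'
#' BED3 for \code{kind = "peaks"}; BED4 for \code{kind = "states"}, whose 4th
#' column is mapped through an alias table onto the 11-level state vocabulary
#' (unknown labels become \code{Others} with a warning).
#'
#' @param path Path to the BED file (0-based half-open).
#' @param kind \code{"peaks"} or \code{"states"}.
#' @param aliases Named character vector mapping raw labels to vocabulary
#'   labels; see \code{\link{defaultStateAliases}}.
#' @return A \code{GRanges}; for states, with a \code{state} metadata column.
#' @export
readIntervals <- function(path, kind = c("peaks", "states"),
                          aliases = defaultStateAliases()) {
  kind <- match.arg(kind)
  raw <- .readTabLines(path, if (kind == "states") 4L else 3L,
                       paste0("BED (", kind, ")"))
  if (nrow(raw) == 0) {
    gr <- GenomicRanges::GRanges()
    if (kind == "states") S4Vectors::mcols(gr)$state <- character(0)
    return(gr)
  }
  start <- .numCol(raw[[2]], "start")
  end <- .numCol(raw[[3]], "end")
  if (any(start < 0)) stop("negative start at data line ", which(start < 0)[1])
  if (any(start >= end))
    stop("start >= end at data line ", which(start >= end)[1])
  gr <- .bedToGRanges(raw[[1]], start, end)
  if (kind == "states") {
    lab <- raw[[4]]
    mapped <- unname(aliases[lab])
    unknown <- is.na(mapped)
    if (any(unknown)) {
      warning("unknown state label(s) mapped to Others: ",
              paste(unique(lab[unknown]), collapse = ", "))
      mapped[unknown] <- "Others"
    }
    S4Vectors::mcols(gr)$state <- mapped
  }
  gr
}

#' Read a TSS table
#'
#' Tab-separated columns gene, chrom, tss (0-based first transcribed base),
#' strand. With \code{policy = "upstream"} (default) a gene with several TSS
#' records keeps the most upstream one (smallest coordinate on +, largest on
#' -); \code{policy = "all"} keeps every record.
#'
#' @param path Path to the TSS TSV (header required).
#' @param policy De-duplication policy, \code{"upstream"} or \code{"all"}.
#' @return data.frame(gene, chrom, tss, strand).
#' @export
readTSS <- function(path, policy = c("upstream", "all")) {
  policy <- match.arg(policy)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("TSS table needs columns: ", paste(need, collapse = ", "))
  df$tss <- as.integer(.numCol(df$tss, "tss"))
  if (!all(df$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'")
  if (policy == "upstream" && anyDuplicated(df$gene)) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$gene), function(i) {
      if (length(i) == 1L) return(i)
      s <- df$strand[i[1]]
      if (s == "+") i[which.min(df$tss[i])] else i[which.max(df$tss[i])]
    }))
    df <- df[sort(keep), , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, need]
}

#' Read an expression table into a SummarizedExperiment
#'
#' TSV with a leading \code{gene} column and one numeric column per sample. An
#' optional sample sheet (TSV: sample, condition, spikein_factor) attaches
#' condition labels and spike-in scale factors as colData; when present,
#' factors must cover every sample and be positive.
#'
#' @param path Path to the expression TSV.
#' @param sampleSheet Optional path to the sample sheet TSV.
#' @return A \code{SummarizedExperiment} with assay \code{"values"}.
#' @export
readExpression <- function(path, sampleSheet = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be named 'gene'")
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression value encountered")
  if (any(m < 0)) stop("negative expression values are not allowed")
  rownames(m) <- df$gene
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  if (!is.null(sampleSheet)) {
    ss <- utils::read.table(sampleSheet, sep = "\t", header = TRUE,
                            quote = "", stringsAsFactors = FALSE)
    if (!all(c("sample", "condition") %in% names(ss)))
      stop("sample sheet needs columns sample, condition")
    missingSamples <- setdiff(colnames(m), ss$sample)
    if (length(missingSamples))
      stop("sample sheet does not cover sample(s): ",
           paste(missingSamples, collapse = ", "))
    ss <- ss[match(colnames(m), ss$sample), , drop = FALSE]
    cd$condition <- ss$condition
    if ("spikein_factor" %in% names(ss)) {
      if (any(is.na(ss$spikein_factor) | ss$spikein_factor <= 0))
        stop("spike-in factors must be positive and cover every sample")
      cd$spikein_factor <- ss$spikein_factor
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(values = m), colData = cd)
}

#' Divide expression values by per-sample spike-in factors
#'
#' @param se SummarizedExperiment from \code{\link{readExpression}} with a
#'   \code{spikein_factor} colData column.
#' @return The SummarizedExperiment with an added \code{normalized} assay.
#' @export
spikeinNormalize <- function(se) {
  f <- SummarizedExperiment::colData(se)$spikein_factor
  if (is.null(f)) stop("no spikein_factor column in colData")
  m <- SummarizedExperiment::assay(se, "values")
  SummarizedExperiment::assay(se, "normalized") <-
    sweep(m, 2, f, "/")
  se
}

#' Read a gene x cell matrix from TSV or MatrixMarket triplet
#'
#' A \code{.mtx} path is read with its 10x-style sidecars
#' (\code{genes.tsv}, \code{barcodes.tsv} in the same directory); any other
#' path is read as a TSV with a leading \code{gene} column.
#'
#' @param path Path to the TSV or .mtx file.
#' @return A numeric matrix, genes in rows, cells in columns.
#' @export
readCellMatrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    d <- dirname(path)
    rownames(m) <- utils::read.table(file.path(d, "genes.tsv"),
                                     stringsAsFactors = FALSE)[[1]]
    colnames(m) <- utils::read.table(file.path(d, "barcodes.tsv"),
                                     stringsAsFactors = FALSE)[[1]]
    return(m)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
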