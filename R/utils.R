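# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do
#' not perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stages of the pipeline draw their own seeds so each stage is independently
#' reproducible: \code{(seed * 101 + sum(utf8ToInt(stage))) mod (2^31 - 1)}.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  as.integer((as.numeric(seed) * 101 + sum(utf8ToInt(stage))) %% (2^31 - 1))
}

# bin id string for a 0-based bin start
.binId <- function(chrom, start) paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE))

# convert 0-based half-open coordinates to GRanges (1-based closed)
.bedToGRanges <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1L, end = end),
                         strand = strand)
}

# deterministic tab-separated writer: no quotes, no row names, '\n' endings
.writeTSV <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names, eol = "\n")
  invisible(path)
}
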