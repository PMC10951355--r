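tssDF <- function(gene, chrom, tss, strand) {
  data.frame(gene = gene, chrom = chrom, tss = tss, strand = strand,
             stringsAsFactors = FALSE)
}

# 0-based half-open view of a GRanges
asBed <- function(gr) {
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

test_that("promoter construction follows strand and clips at boundaries", {
  tss <- tssDF(c("gP", "gM", "gC"), "chr1", c(10000L, 10000L, 1000L),
               c("+", "-", "+"))
  pr <- makePromoters(tss, up = 2500, down = 100)
  bed <- asBed(pr)
  expect_equal(bed[1, ], data.frame(start = 7500L, end = 10100L),
               ignore_attr = TRUE)        # + strand: [tss-up, tss+down)
  expect_equal(bed[2, ], data.frame(start = 9900L, end = 12500L),
               ignore_attr = TRUE)        # - strand mirror
  expect_equal(bed[3, ], data.frame(start = 0L, end = 1100L),
               ignore_attr = TRUE)        # clipped at 0
  # unclipped widths are up + down on both strands
  expect_equal(IRanges::width(pr)[1:2], c(2600L, 2600L))
  expect_error(makePromoters(tss, up = 0, down = 0), "degenerate")
})

test_that("element classification applies the exclusion window half-open", {
  pr <- makePromoters(tssDF("g1", "chr1", 10000L, "+"))   # [7500, 10100)
  farPeak <- gr0("chr1", 20000, 20500)
  nearPeak <- gr0("chr1", 11000, 11400)
  abutPeak <- gr0("chr1", 10100, 10600)  # end-abutting the promoter
  el <- classifyElements(c(farPeak, nearPeak), pr, window = 1500)
  expect_equal(length(el$enhancers), 1L)           # gap 9900 > 1500
  expect_equal(asBed(el$enhancers)$start, 20000)   # near peak absorbed
  el0 <- classifyElements(abutPeak, pr, window = 0)
  expect_equal(length(el0$enhancers), 1L)          # half-open: no overlap
  el1 <- classifyElements(abutPeak, pr, window = 1)
  expect_equal(length(el1$enhancers), 0L)
})

test_that("bin annotation applies P > E precedence and collects gene sets", {
  scheme <- BinScheme(10000, c(chr1 = 100000))
  # two genes share one promoter bin; an enhancer overlaps the same bin
  tss <- tssDF(c("g1", "g2", "g3"), "chr1", c(5000L, 8000L, 25000L),
               c("+", "+", "+"))
  pr <- makePromoters(tss)
  enh <- gr0("chr1", c(6000, 12000), c(6500, 12500))
  el <- list(promoters = pr, enhancers = enh)
  ann <- makeAnnotation(c("chr1:0", "chr1:10000", "chr1:30000"))
  loops <- data.frame(chrom1 = "chr1", start1 = c(0L, 10000L),
                      end1 = c(10000L, 20000L), chrom2 = "chr1",
                      start2 = c(10000L, 30000L), end2 = c(20000L, 40000L),
                      count = c(2L, 3L), q = 0.001,
                      bin1 = c("chr1:0", "chr1:10000"),
                      bin2 = c("chr1:10000", "chr1:30000"))
  out <- annotateBins(scheme, loops, el)
  expect_equal(out$class, c("P", "E", "other"))
  expect_equal(out$genes[1], "g1,g2")      # promoter of 2 genes
  expect_equal(out$genes[2], "")
  # only loop-participating bins are annotated
  expect_equal(nrow(out), 3L)
})

test_that("state assignment honours the 11-level hierarchy and is idempotent", {
  ann <- makeAnnotation(c("b1", "b2", "b3", "b4"))
  states <- gr0("chr1", c(0, 0, 10000, 20000), c(5000, 6000, 15000, 25000))
  S4Vectors::mcols(states)$state <-
    c("Heterochromatin", "ActivePromoter", "Insulator", "WeakEnhancer")
  se <- gr0("chr1", 100, 400)
  out <- assignStates(ann, states, superEnhancers = se)
  expect_equal(out$state,
               c("SuperEnhancer",  # rank 1 beats ActivePromoter/Heterochrom.
                 "Insulator",      # only overlap
                 "WeakEnhancer",   # only overlap
                 "Others"))        # no overlap
  # ActivePromoter (rank 3) beats WeakEnhancer (rank 6)
  states2 <- gr0("chr1", c(0, 0), c(5000, 5000))
  S4Vectors::mcols(states2)$state <- c("WeakEnhancer", "ActivePromoter")
  out2 <- assignStates(ann, states2)
  expect_equal(out2$state[1], "ActivePromoter")
  # idempotent: reapplying yields the same assignment
  expect_identical(assignStates(out, states, superEnhancers = se), out)
  # total: every bin has exactly one state from the vocabulary
  expect_true(all(out$state %in% stateLevels()))
})

test_that("same-rank ties resolve by largest overlap", {
  ann <- makeAnnotation("b1")
  states <- gr0("chr1", c(0, 5000), c(2000, 10000))
  S4Vectors::mcols(states)$state <- c("Insulator", "Heterochromatin")
  # force same rank: two Insulator intervals of different overlap
  S4Vectors::mcols(states)$state <- c("Insulator", "Insulator")
  out <- assignStates(ann, states)
  expect_equal(out$state, "Insulator")
  st2 <- gr0("chr1", c(0, 1000), c(2000, 9000))
  S4Vectors::mcols(st2)$state <- c("Heterochromatin", "Heterochromatin")
  expect_equal(assignStates(ann, st2)$state, "Heterochromatin")
})

test_that("peak breadth at TSS picks the widest covering peak", {
  tss <- tssDF(c("g1", "g2", "g3"), "chr1", c(1000L, 50000L, 70000L),
               c("+", "+", "+"))
  peaks <- gr0("chr1", c(900, 800, 69000), c(4100, 5800, 74000))
  b <- breadthAtTSS(peaks, tss)
  expect_equal(unname(b["g1"]), 5000)  # widest of 3200 and 5000
  expect_true(is.na(b["g2"]))          # no covering peak
  expect_equal(unname(b["g3"]), 5000)
  expect_equal(unname(breadthAtTSS(peaks[1], tss)["g1"]), 3200)
})

test_that("promoter and element geometry match a per-base oracle", {
  # 10 kb toy genome, random layouts, both strands, windows 0 and 1500
  genomeLen <- 10000L
  for (seed in 1:20) {
    layout <- withr::with_seed(seed, {
      nG <- sample(2:4, 1)
      nP <- sample(2:5, 1)
      tss <- tssDF(paste0("g", seq_len(nG)), "chr1",
                   as.integer(sample(200:9800, nG)),
                   sample(c("+", "-"), nG, replace = TRUE))
      ps <- sort(sample(0:(genomeLen - 300), nP))
      list(tss = tss, peakStart = ps,
           peakEnd = pmin(ps + sample(50:2000, nP, replace = TRUE),
                          genomeLen),
           up = sample(c(500L, 2500L), 1), down = sample(c(100L, 500L), 1))
    })
    pr <- makePromoters(layout$tss, layout$up, layout$down,
                        c(chr1 = genomeLen))
    # per-base promoter coverage oracle
    cov <- logical(genomeLen)
    for (i in seq_len(nrow(layout$tss))) {
      t0 <- layout$tss$tss[i]
      if (layout$tss$strand[i] == "+") {
        lo <- max(t0 - layout$up, 0); hi <- min(t0 + layout$down, genomeLen)
      } else {
        lo <- max(t0 - layout$down, 0); hi <- min(t0 + layout$up, genomeLen)
      }
      if (lo < hi) cov[(lo + 1):hi] <- TRUE
    }
    prBed <- asBed(pr)
    covPkg <- logical(genomeLen)
    for (i in seq_len(nrow(prBed)))
      covPkg[(prBed$start[i] + 1):prBed$end[i]] <- TRUE
    expect_identical(covPkg, cov, label = paste("promoter layout", seed))

    peaks <- gr0("chr1", layout$peakStart, layout$peakEnd)
    for (window in c(0L, 1500L)) {
      el <- classifyElements(peaks, pr, window)
      isEnh <- vapply(seq_along(peaks), function(i) {
        lo <- max(layout$peakStart[i] - window, 0)
        hi <- min(layout$peakEnd[i] + window, genomeLen)
        !any(cov[(lo + 1):hi])
      }, TRUE)
      expect_identical(asBed(el$enhancers)$start,
                       layout$peakStart[isEnh],
                       label = paste("elements layout", seed, "window", window))
    }
  }
})
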