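# helper: SummarizedExperiment for one gene per row with three conditions
nascentSE <- function(values, genes = sprintf("g%02d", seq_len(nrow(values))),
                      factors = rep(1, 3)) {
  m <- as.matrix(values)
  colnames(m) <- c("naive_veh", "naive_atRA", "primed_atRA")
  rownames(m) <- genes
  SummarizedExperiment::SummarizedExperiment(
    assays = list(values = m),
    colData = S4Vectors::DataFrame(
      condition = colnames(m), spikein_factor = factors,
      row.names = colnames(m)))
}

test_that("response classification applies the two-threshold log2FC rule", {
  se <- nascentSE(rbind(c(10, 20, 50),   # lfc_r = 1, lfc_m ~ 1.32 -> memory
                        c(10, 20, 22),   # lfc_m ~ 0.14 -> responsive
                        c(10, 10, 10)))  # flat -> nonresponsive
  rc <- classifyResponse(se, lfcCut = 0.5, pseudocount = 0)
  expect_equal(rc$class, c("memory", "responsive", "nonresponsive"))
  expect_equal(rc$lfc_r[1], 1)
  expect_equal(rc$lfc_m[1], log2(50 / 20))
  # classes partition genes and memory implies responsive-by-lfc_r
  expect_true(all(rc$lfc_r[rc$class == "memory"] > 0.5))
  # +Inf cut -> all nonresponsive; -Inf cut with increasing means -> memory
  expect_true(all(classifyResponse(se, lfcCut = Inf)$class ==
                    "nonresponsive"))
  se2 <- nascentSE(rbind(c(1, 2, 4)))
  expect_equal(classifyResponse(se2, lfcCut = -Inf)$class, "memory")
  # spike-in factors are divided out before fold changes
  se3 <- nascentSE(rbind(c(10, 40, 50)), factors = c(1, 2, 1))
  rc3 <- classifyResponse(se3, pseudocount = 0)
  expect_equal(rc3$lfc_r, 1)   # 40/2 = 20 vs 10
  # missing condition errors
  bad <- se
  SummarizedExperiment::colData(bad)$condition[3] <- "naive_atRA"
  expect_error(classifyResponse(bad), "conditions")
  zero <- nascentSE(rbind(c(0, 1, 2)))
  expect_error(classifyResponse(zero, pseudocount = 0), "pseudocount")
})

test_that("iCD extraction returns the promoter's connected component", {
  # toy net is fully connected: gA's iCD covers all four bins
  net <- toyNetwork()
  icd <- extractICD(net, "gA")
  expect_setequal(icdNodes(icd), paste0("b", 1:4))
  expect_equal(icdGene(icd), "gA")
  # nodes come out in genomic order
  expect_equal(icdNodes(icd), paste0("b", 1:4))
  # two disjoint components: the other component is excluded
  ann <- makeAnnotation(paste0("c", 1:5),
                        classes = c("P", "E", "P", "E", "E"),
                        genes = c("g1", "", "g2", "", ""))
  loops <- makeLoops(ann, c("c1", "c3", "c4"), c("c2", "c4", "c5"),
                     c(2, 3, 4))
  net2 <- buildNetwork(loops, ann, 10000)
  icd1 <- extractICD(net2, "g1")
  expect_setequal(icdNodes(icd1), c("c1", "c2"))
  icd2 <- extractICD(net2, "g2")
  expect_setequal(icdNodes(icd2), c("c3", "c4", "c5"))
  expect_error(extractICD(net2, "gX"), "no promoter bin")
  expect_warning(res <- extractICDs(net2, c("g1", "gX")), "absent")
  expect_equal(names(res), "g1")
})

test_that("iCD clustering separates bridged cliques and is deterministic", {
  # two 4-cliques joined by one bridge edge
  bins <- sprintf("q%02d", 1:8)
  ann <- makeAnnotation(bins, classes = c("P", rep("E", 7)),
                        genes = c("g1", rep("", 7)))
  cliqueEdges <- function(members) t(combn(members, 2))
  e1 <- cliqueEdges(bins[1:4]); e2 <- cliqueEdges(bins[5:8])
  ee <- rbind(e1, e2, c(bins[4], bins[5]))
  loops <- makeLoops(ann, ee[, 1], ee[, 2], rep(2, nrow(ee)))
  net <- buildNetwork(loops, ann, 10000)
  icd <- extractICD(net, "g1")
  cl <- clusterICD(icd, seed = 4)
  expect_equal(length(unique(cl$coarse)), 2L)
  expect_equal(length(unique(cl$coarse[bins[1:4]])), 1L)
  expect_equal(length(unique(cl$coarse[bins[5:8]])), 1L)
  expect_gt(cl$modularity, 0.2)
  expect_identical(cl, clusterICD(icd, seed = 4))
  # complete graph: one community
  eK <- cliqueEdges(bins[1:5])
  annK <- makeAnnotation(bins[1:5], classes = c("P", rep("E", 4)),
                         genes = c("g1", rep("", 4)))
  netK <- buildNetwork(makeLoops(annK, eK[, 1], eK[, 2], rep(1, nrow(eK))),
                       annK, 10000)
  clK <- clusterICD(extractICD(netK, "g1"), seed = 4)
  expect_equal(length(unique(clK$coarse)), 1L)
  # chain-only nodes never leave their chain neighbours at the fine level
  expect_true(all(tapply(cl$fine, cl$coarse, function(x) length(unique(x))) >= 1))
})

test_that("erosion removes low-weight edges and tracks survival", {
  # memory iCD with edges {1,1,2}; responsive iCD with a single edge {8}
  annM <- makeAnnotation(paste0("m", 1:4), classes = c("P", "E", "E", "E"),
                         genes = c("gm", "", "", ""))
  icdM <- extractICD(buildNetwork(
    makeLoops(annM, c("m1", "m1", "m1"), c("m2", "m3", "m4"), c(1, 1, 2)),
    annM, 10000), "gm")
  annR <- makeAnnotation(paste0("r", 1:2), classes = c("P", "E"),
                         genes = c("gr", ""))
  icdR <- extractICD(buildNetwork(makeLoops(annR, "r1", "r2", 8),
                                  annR, 10000), "gr")
  groups <- c(gm = "memory", gr = "responsive")
  # global weights chosen so the 75th percentile threshold is 3
  ec <- erosionAnalysis(list(gm = icdM, gr = icdR), groups,
                        globalWeights = c(1, 2, 3, 8), percentiles = 75)
  expect_equal(ec$threshold, c(3, 3))
  expect_equal(ec$promoter_fraction[ec$group == "memory"], 0)
  expect_equal(ec$promoter_fraction[ec$group == "responsive"], 1)
  # threshold below every weight retains everything
  ec0 <- erosionAnalysis(list(gm = icdM, gr = icdR), groups,
                         globalWeights = c(1, 2, 3, 8), percentiles = 10)
  expect_true(all(ec0$region_fraction == 1))
  expect_true(all(ec0$promoter_fraction == 1))
  # fractions never increase with the threshold
  ecAll <- erosionAnalysis(list(gm = icdM, gr = icdR), groups,
                           globalWeights = c(1, 1, 2, 8))
  for (grp in c("memory", "responsive")) {
    sub <- ecAll[ecAll$group == grp, ]
    expect_true(all(diff(sub$region_fraction) <= 1e-12))
    expect_true(all(diff(sub$promoter_fraction) <= 1e-12))
  }
})

test_that("state strength is the filtered/unfiltered fraction ratio", {
  # 10-node chain, heavy edges confined to nodes 1-3, SE on {n2,n3,n9,n10}
  bins <- sprintf("n%02d", 1:10)
  states <- ifelse(bins %in% c("n02", "n03", "n09", "n10"),
                   "SuperEnhancer", "Others")
  ann <- makeAnnotation(bins, classes = c("P", rep("E", 9)),
                        genes = c("g1", rep("", 9)), states = states)
  from <- bins[-10]; to <- bins[-1]
  w <- c(10, 10, rep(1, 7))          # n1-n2 and n2-n3 heavy
  net <- buildNetwork(makeLoops(ann, from, to, w), ann, 10000)
  icd <- extractICD(net, "g1")
  st <- stateStrength(list(g1 = icd), c(g1 = "memory"),
                      globalWeights = rep(c(1, 10), c(5, 5)),
                      percentile = 90)
  se <- st[st$state == "SuperEnhancer", ]
  expect_equal(se$frac_unfiltered, 4 / 10)
  expect_equal(se$frac_filtered, 2 / 3)    # survivors n1, n2, n3
  expect_equal(se$strength, (2 / 3) / (4 / 10))
  expect_equal(se$strength_reciprocal, 1 / se$strength)
  # a uniform single-state annotation has strength 1
  annU <- makeAnnotation(bins[1:3], classes = c("P", "E", "E"),
                         genes = c("g1", "", ""),
                         states = rep("Heterochromatin", 3))
  netU <- buildNetwork(makeLoops(annU, bins[1:2], bins[2:3], c(1, 10)),
                       annU, 10000)
  stU <- stateStrength(list(g1 = extractICD(netU, "g1")), c(g1 = "memory"),
                       globalWeights = rep(c(1, 10), c(5, 5)))
  expect_equal(stU$strength, 1)
})
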