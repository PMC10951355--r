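---
title: "chromICD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromICD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the default parameters, the
synthetic-data generator, and the numerical choices made in chromICD. It
contains no empirical claims beyond what the package's tests and
`scripts/acceptance.R` compute.

# Model

## From loops to a network

Input loops are BEDPE-like records (`chrom1 start1 end1 chrom2 start2 end2
contact_count q_value`, 0-based half-open). `readLoops()` keeps records with
`q_value <= qThreshold` (default 0.01), validates that both anchors align to
the bin scheme, orders each pair so that the lexicographically smaller anchor
comes first, and merges duplicate unordered pairs by summing contact counts
(keeping the smaller q). Filtering happens *before* merging, so an
insignificant duplicate never contributes counts. `buildNetwork()` turns the
result into an undirected simple `igraph` whose vertices are bins and whose
edge weights are the merged contact counts.

## Node annotation

Promoters are `[TSS - up, TSS + down)` with `up = 2500`, `down = 100` on the
plus strand and the mirror image on the minus strand, clipped at chromosome
boundaries. Enhancers are accessibility peaks that, after symmetric extension
by `window = 1500` bp, overlap no promoter. A bin overlapping any promoter is
class `P`; otherwise, overlapping any enhancer, class `E`; otherwise
`other` — so `P` takes precedence over `E`. Chromatin states come from an
11-level vocabulary ranked

> SuperEnhancer ≻ BroadPeak ≻ ActivePromoter ≻ ActiveEnhancer ≻
> WeakPromoter ≻ WeakEnhancer ≻ InactivePoisedPromoter ≻ Insulator ≻
> PolycombRepressed ≻ Heterochromatin ≻ Others

and each bin receives the highest-ranked state overlapping it; rank ties are
broken by largest overlap, then by position. `assignStates()` is idempotent.

## CRE-removal permutation test

The observed statistic is the average degree (`2|E| / |V|`) of the network
after deleting the candidate CRE nodes (isolated survivors are retained in
the denominator). The null distribution comes from `nPerm = 1000` deletions
of uniformly sampled node sets of the same size. The empirical p-value is the
fraction of null statistics *strictly below* the observed value, with no
continuity correction; an exact zero is reported as `p < 1/nPerm`.
Internally the statistic is computed by edge-survival counting
(an edge survives iff neither endpoint is removed), which avoids rebuilding
the graph per permutation.

## Connectivity and expression

A gene's connectivity is the summed weight of the *distinct* edges incident
to its promoter bins; an edge joining two bins of the same gene counts once.
Genes are ranked and split into 10 equal-count rank deciles (ties broken
deterministically by gene id, with a warning). Per decile we report
P(expression > population mean), computed directly and through Bayes'
theorem — P(decile | above) · P(above) / P(decile) — and the implementation
verifies the two routes agree to 1e-12.

Consensus k-means (`k = 3`, `repeats = 10`) operates on row z-scores:
zero-variance rows are dropped with a warning, each repeat is seeded
deterministically, a consensus co-assignment matrix keeps runs agreeing with
the majority partition on at least half the pairs, and the returned labelling
is the eligible run with the lowest within-cluster sum of squares, with
labels renumbered by the cluster mean of the first sample.

## Memory classification

Nascent counts are divided by per-sample spike-in factors, replicates are
averaged per condition, and with pseudocount `ps = 0.1`:

- `lfc_r = log2((naive_stim + ps) / (naive_vehicle + ps))`
- `lfc_m = log2((primed_stim + ps) / (naive_stim + ps))`

A gene is *responsive* when `lfc_r > 0.5` and *memory* when additionally
`lfc_m > 0.5`; everything else is *nonresponsive*.

## iCDs, communities, erosion, and state strength

The iCD of a gene is the connected component containing its promoter bin,
restricted to the promoter's chromosome, with nodes in genomic order.
`clusterICD()` runs seeded Louvain on a combined graph: the interaction layer
plus a genomic-adjacency chain linking consecutive bins, the chain edges
weighted by the median interaction weight (floored at 1) so they neither
dominate nor vanish. The coarse level is the Louvain partition of the
combined graph; the fine level re-runs Louvain on the interaction layer
within each coarse community, attaching chain-only bins to their nearest
chain neighbour.

Erosion thresholds are nearest-rank (type-1) percentiles of the *global*
edge-weight multiset, so every group is eroded against the same scale. At
each threshold, edges with weight below the threshold are removed; a bin
(region) survives iff it keeps at least one incident edge, and a gene's
promoter survives iff its promoter bin does. Fractions are pooled over the
unique bins of all iCDs in a group (a per-iCD averaging mode is available via
`perICD = TRUE`); single-node iCDs carry no edges and are excluded with a
warning.

State strength at a percentile (default the 90th) compares, per group and
chromatin state, the fraction of surviving bins in that state with the same
fraction before filtering; both the ratio and its reciprocal are reported so
either orientation can be read off directly.

# Default parameters

| Parameter | Default | Role |
|---|---|---|
| `binSize` | 10000 | bin scheme used throughout |
| `qThreshold` | 0.01 | loop significance cut |
| `up`, `down` | 2500, 100 | promoter window around the TSS |
| `window` | 1500 | promoter-exclusion window for enhancers |
| `nPerm` | 1000 | permutations in the CRE-removal test |
| `nBins` | 10 | connectivity deciles |
| `k`, `repeats` | 3, 10 | consensus k-means |
| `lfcCut`, `pseudocount` | 0.5, 0.1 | memory classification |
| `percentiles` | 10–90 by 10 | erosion thresholds |
| `percentile` | 90 | state-strength threshold |
| `n` | 150 | top-N signature size |

# The synthetic-data generator

`simulateBundle()` writes a complete, internally consistent input bundle
(loops, peaks, TSS table, state segments, super-enhancer and broad domains,
CRE set, expression, nascent counts with a sample sheet, a cell matrix, and
truth tables) from a single seed. Its defaults describe the study conditions
the package is exercised under; they were chosen to make the planted
structure identifiable, not to mimic any particular dataset:

- **Genome and territories.** Two chromosomes of 25 Mb at 10 kb bins. Each of
  the 300 genes owns a disjoint 16-bin territory (1 promoter bin + 15 local
  enhancer bins). Territories are disjoint so that each promoter's connected
  component stays local; with a shared enhancer pool the loop graph collapses
  into one giant component and per-group contrasts in erosion and state
  strength are erased by construction.
- **Class-specific contact structure.** Memory promoters receive 8 low-weight
  edges (weights `1 + Poisson(1)`), responsive promoters 2 heavy edges
  (`1 + Poisson(7)`), other promoters 3 mid-weight edges (`1 + Poisson(3)`).
  This encodes the hypothesis under study — memory iCDs are broad but
  weakly connected, responsive iCDs narrow but strong — as a generative
  assumption whose recovery the tests then verify.
- **Super-enhancer planting.** With probability 0.3 a memory promoter gains
  one extra heavy edge whose partner bin is annotated `SuperEnhancer` with
  probability 0.6, against a background SuperEnhancer rate of 0.1. This makes
  state strength a meaningful contrast rather than a tautology: most memory
  bins carry no super-enhancer.
- **Hub CREs.** 10 bins receive 20 extra edges each, confined to ±12 bins so
  hubs do not bridge territories.
- **Expression coupling.** Gene expression is Poisson with log-mean
  `baseline · exp(0.8 · log1p(connectivity))`; setting the coupling to 0
  yields a flat decile profile (verified in the tests).
- **Nascent design.** Condition means (vehicle, naive-stim, primed-stim) are
  (10, 25, 60) for memory, (10, 25, 27) for responsive, (10, 10, 10) for
  nonresponsive genes, with log-normal noise (`sdlog = 0.05`) and spike-in
  factors `(1, 1, 1.25, 1.25, 0.8, 0.8)` across the six samples.
- **Decoys.** 5% extra loops with `q` in (0.02, 0.5) exercise the
  significance filter.

# Numerical choices

- **Quantiles** are nearest-rank (`stats::quantile(type = 1)`), so thresholds
  are always observed weights and erosion behaves as a step function of the
  percentile.
- **Ties** in ranks (deciles, top-N signatures) are broken deterministically
  by gene id and flagged with a warning, never silently randomised.
- **Seeding.** All stochastic steps take explicit seeds; `stageSeed(seed,
  stage)` derives per-stage seeds as `(seed * 101 + sum(utf8ToInt(stage)))
  mod (2^31 - 1)`, keeping every derived seed in the 32-bit range.
  `withSeed()` saves and restores `.Random.seed`, so library calls never
  perturb the caller's random-number state.
- **Strict-inequality p-values.** `creRemovalTest()` counts `null < observed`
  with no pseudo-count; a tie-inclusive variant (`tieInclusive = TRUE`) is
  available for sensitivity analysis and is never smaller than the strict
  version.
- **Exact round-trips.** `writeLoops()` prints q-values with `%.15g`, so
  `readLoops(writeLoops(x))` reproduces `x` exactly.

# Limitations

- The network is built from intra-chromosomal loops by default
  (`allowTrans = FALSE`); trans contacts are supported at the I/O layer but
  untested as network edges.
- iCDs are defined purely by connectivity; there is no statistical model of
  domain boundaries, and a single spurious loop can merge two domains.
- The erosion and strength contrasts are descriptive fractions, not
  significance tests; they come with no confidence intervals.
- The generator plants structure at the level of edge counts and weights; it
  does not model distance-decay of contact frequency, replicate-level loop
  calling, or copy-number effects.
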