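---
title: "Classifying and characterizing tissue-shared versus tissue-specific ChIP binding"
author: "discChIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and characterizing tissue-shared versus tissue-specific ChIP binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discChIP)
library(GenomicRanges)
```

## The problem

A transcription factor assayed by ChIP in two tissues -- here the wing
(W) and eye-antenna (EA) imaginal discs of *Drosophila*, for the
Hippo-pathway regulators Scalloped (Sd), Homothorax (Hth) and the
coactivator Yorkie (Yki) -- yields two peak lists that cannot be
compared naively: a binding event just under the significance cutoff in
one tissue is not evidence of tissue-specific binding. `discChIP`
implements the dual false-discovery-rate threshold rule that addresses
this, and the downstream analyses that characterize the two resulting
classes of binding events: interval co-occurrence statistics,
genomic-region breakdown, degenerate-motif content, central motif
enrichment, evolutionary conservation, enhancer-catalog overlap, and
enrichment across the five-state chromatin segmentation
(YELLOW/RED active, BLUE Polycomb, GREEN/BLACK silent).

## The classification rule

Each tissue's peaks are called at two tiers: stringent (1% FDR) and
permissive (25% FDR). A stringent peak of the home tissue is

* **SPECIFIC** when it overlaps no permissive peak of the partner
  tissue, and
* **SHARED** when it overlaps at least one.

Requiring absence even at the permissive tier prevents a peak that
narrowly missed the stringent cutoff in the partner tissue from being
miscalled as tissue-specific. Overlap means at least one shared base;
no reciprocal-fraction requirement is imposed. The permissive tier must
nest the stringent tier (every FDR1 peak overlaps an FDR25 peak); this
is enforced when a `DualTierPeaks` object is built and violations are
reported, never repaired silently.

Both tissues' stringent peaks are labeled independently, so a shared
event is counted once per tissue; `sharedConsensus()` collapses the two
lists into one merged region set for downstream stages that need a
single shared-class list.

```{r classify-example}
a <- DualTierPeaks("Sd", "W",
  fdr1  = GRanges("chr2L", IRanges(c(101, 1001), c(300, 1200))),
  fdr25 = GRanges("chr2L", IRanges(c(81, 981), c(320, 1220))))
b <- DualTierPeaks("Sd", "EA",
  fdr1  = GRanges("chr2L", IRanges(151, 350)),
  fdr25 = GRanges("chr2L", IRanges(131, 370)))
calls <- classifySpecificity(a, b)
specificityCounts(calls)
```

## Coordinates

Intervals live in `GRanges` (1-based, closed), the Bioconductor
convention; BED input and output is 0-based half-open on disk with
`rtracklayer` converting at the boundary, and GFF3 is read natively.
Keeping a single internal convention removes off-by-one drift; the
contracts that matter are tested explicitly: abutting intervals do not
overlap, and the center of a peak spanning 0-based `[s, e)` is base
`floor((s+e)/2)` (the left of the two middle bases for even widths --
the rule needs a tie-break and this is the one used everywhere).
Chromosome names match by exact string comparison; no "chr" aliasing
is attempted.

## Co-occurrence statistics

Overlap significance between two interval sets uses a binned
hypergeometric null: the genome is tiled into fixed-width bins (1 kb by
default, configurable), each set marks the bins it touches, and with
`N` bins, `n` hit by A, `K` hit by B and `k` hit by both, the expected
double-hit count is `nK/N` and the p-value is the upper tail
`P(X >= k)`, `X ~ Hypergeometric(N, K, n)`. The bin is the exchangeable
unit rather than the peak, which makes the null enumerable and lets the
tests check the implementation against a direct tail-summation oracle
and a label-permutation simulation. p-values are floored at the
smallest positive double so `-ln(p)` stays finite. The null ignores
GC content and mappability on purpose: inputs here are desk-scale and
the statistic is meant to be auditable.

Whether an "expected overlap" should account for peak widths as well
as counts is a genuinely open design choice; the bin-level construction
above is this package's answer, and peak widths enter only through how
many bins a set touches.

## Genomic-region breakdown and target logic

Every peak gets exactly one region label, decided at its center with
precedence PROMOTER > EXON > INTRON > INTERGENIC, so the fractions form
a true partition. The promoter is the strand-aware 1 kb window
immediately upstream of a TSS. Genes are targeted by a peak when the
peak overlaps the gene body or reaches within 10 kb of the TSS (both
parameters exposed); each targeted gene is then classed as
`SHARED_ONLY`, `SHARED_PLUS_SPECIFIC` or `SPECIFIC_ONLY` from the
labels of its peaks. The 10 kb window is a deliberate simplification:
real enhancers can act from much farther away (the *bantam* enhancers
sit more than 30 kb out), so genes regulated exclusively at long range
are missed; the window is a flag, not a constant. Gene-set enrichment
is the upper-tail hypergeometric per set with Benjamini-Hochberg
correction across sets.

## Motif analyses

Consensus matching is binary over the IUPAC alphabet, on both strands;
spaced dimers such as the Hth-Exd site `TGAY{N0-2}TGAY` take an
unconstrained spacer of 0-2 bases between the half-sites. A sequence
`N` is matched by no pattern symbol except `N`. The scanner reports
every admissible (start, spacer, strand) combination; "containing the
motif" for a peak means at least one match anywhere inside the called
peak interval. Per-state containment fractions are compared with
Fisher's exact test (two-sided, minimum-likelihood), the natural exact
test for a 2x2 containment table.

Central enrichment follows the binomial construction: peaks are resized
to a common length around their centers, each motif keeps its single
best site per sequence (ties broken toward the center, then leftmost),
and a center-symmetric window of start positions is tested with an
upper-tail binomial whose success probability is the window's share of
admissible starts. The E-value multiplies the p-value by the motif
library size (460 for a JASPAR-core-sized library) and E <= 10 flags
significance. When several candidate windows are scanned the reported
best-window p-value is optimistic, as in the tool this mirrors; the
calibration property in the test suite therefore evaluates a single
fixed window, where the p-value is exactly the binomial tail. Because
that tail is discrete, uniformity under the null is only approximate
at small sequence counts; the calibration test uses 400 sequences per
set so the discreteness is well below the resolution of a
Kolmogorov-Smirnov comparison against the continuous uniform. PWM
motifs (minimal MEME text format) are scored as log-odds against a
uniform 0.25 background.

`mutateSites()` supports the enhancer-dissection workflow: given scan
matches and same-length replacements it rewrites the sites, reports the
total substitution count, and a re-scan of the mutant verifies the
sites are gone (the wild-type to mutant Hth site `GACAG -> GGGGG` is a
3-substitution change).

## Conservation and chromatin state

`profileScores()` averages a per-base track (e.g. PhastCons, in [0,1])
over +/-500 bp around peak centers; track gaps are missing data, not
zeros, and each offset keeps its own contributing count.
`findPerfectRuns()` recovers ultraconserved elements -- maximal runs of
at least 50 bp of perfect cross-species identity -- from a binary
identity track, so synthetic tests need no external element list; real
analyses usually supply UCEs as a BED input instead. Chromatin-state
composition assigns each peak the state at its center (exclusive, sums
to one; centers in segmentation gaps go to an UNASSIGNED bucket with a
warning) and state enrichment reuses the binned hypergeometric
machinery against each state's segments. An any-overlap counting mode
is available behind a flag since a peak can straddle a state boundary.

## The synthetic-data generator

`generateBundle()` emits every input the pipeline consumes -- genome
FASTA, chromosome sizes, gene models, four peak BEDs per factor,
segmentation, conservation bedGraph, UCE BED, enhancer catalog,
gene-set library, motif list -- plus a JSON truth manifest, all a pure
function of the seed (independent sub-seeds per output stream, so
adding a stream never perturbs the others). Peaks occupy disjoint
fixed-width slots: shared sites carry jittered, overlapping peaks at
both tiers in both tissues, specific sites carry peaks in one tissue
only, and permissive-only "inflation" peaks occupy their own slots, so
the classifier's ground truth is exact by construction rather than
approximate. Chromatin states are drawn per slot; peak classes choose
slots with class-specific state biases. Gene structures are templated
around peak centers to realize the drawn region class exactly, with
extents bounded so no feature can reach a neighboring slot's center.
Motif-bearing windows are rejection-sampled to contain no match for any
factor present at the slot, then instances are planted at the
configured per-state rates; the windows over-cover the peaks by a
margin so no chance match can straddle the junction with the untouched
background. Conservation is piecewise-constant (background 0.10, inside
peaks 0.35 for shared and 0.75 for specific sites) and UCEs are planted
under 30% of specific and 5% of shared sites.

The default configuration is the "fig-mimic" scenario, the study
regime the package's acceptance checks run under: for each
sequence-specific factor 3500 wing FDR1 events of which 1500 are shared
(so 2000 wing-specific) against 150 eye-antenna-specific; a
coactivator-like factor with 2500 shared and 150 specific events per
tissue; a 46% promoter share for shared sites versus an
intron/intergenic-dominated specific class; shared sites biased to
YELLOW (55%) and specific sites to BLUE (32%) chromatin; and motif
plant rates of 0.51/0.45/0.37 in BLUE/RED/YELLOW. The genome is six
7.5 Mb chromosomes of i.i.d. uniform A/C/G/T -- the simplest background
consistent with binary consensus matching. What the generator does not
emulate is worth stating: real peak-width and score distributions,
sequence composition (GC skew, repeats), correlated placement of genes
and regulatory DNA, and partially overlapping peaks between unrelated
factors. Passing recovery tests therefore demonstrates correctness of
the pipeline's logic under known truth, not robustness to every
property of real ChIP data.

`validateManifest()` closes the loop: it reloads a bundle and
re-verifies every machine-checkable claim (tier nesting,
classification truth, per-peak state, UCE and motif claims by
re-scanning) and names the offending record on failure.

## The orchestrator

`runAll()` executes classification, co-occurrence matrices, region
breakdown, target logic and gene-set enrichment, motif fractions with
a BLUE-versus-YELLOW contrast, conservation profiles, UCE fractions,
state enrichment, and the enhancer-catalog summary, writing plain TSVs
plus a JSON report. Stages recompute rather than cache; inputs are
desk-scale and caching would only add state. Missing optional inputs
skip their stage with an explicit notice in the report. The analysis
draws no random numbers and the report carries no wall-clock state, so
a rerun on the same inputs is byte-identical; the provenance block
records the package version and a hash of the analysis parameters
(excluding the output directory). Every threshold with a
default not fixed by any published convention -- bin width 1 kb, promoter window 1 kb,
target distance 10 kb, profile half-width 500 bp, UCE length 50 bp,
E-value threshold 10 -- is a visible parameter, logged at run time,
never a buried constant.

## Problem sizes and limitations

The test suite exercises the full fig-mimic scale (about 16,000 peaks
on a 45 Mb genome) once, and smaller seeded bundles everywhere else;
oracle-equivalence checks run the hypergeometric and Fisher statistics
against independent enumeration to 1e-10, the scanner against a
regex-engine oracle on 10^4 random sequences, and interval merging
against a positionwise-union oracle.

Known limitations: the co-occurrence null is bin-based and unmatched
for sequence composition; target assignment is window-based; the
generator's background sequence is compositionally uniform; HOT-region
discovery, PWM curation and raw tiling-array peak calling are out of
scope (peak calls, segmentations, conservation tracks and catalogs are
consumed as inputs). Whether a peak straddling two chromatin states
should count once or twice is genuinely ambiguous; the exclusive
center rule is the default and the alternative is a flag.
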