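# Shared fixtures built in code; the small bundle is generated once per
# session and reused.

toyAssembly <- function(len = 20000, chroms = "chr1") {
  GenomeAssembly(stats::setNames(rep(len, length(chroms)), chroms))
}

# A random but always-consistent dual-tier two-tissue fixture for the
# classifier: peaks on disjoint 1-kb slots, a known subset shared.
randomDualTierFixture <- function(seed, nA = 60, nB = 40, nShared = 25,
                                  factorName = "Sd") {
  set.seed(seed)
  nSlots <- nA + nB + 20
  slots <- sample(seq_len(nSlots)) * 1000L
  centersShared <- slots[seq_len(nShared)]
  centersAonly <- slots[nShared + seq_len(nA - nShared)]
  centersBonly <- slots[nA + seq_len(nB - nShared)]
  mk <- function(centers, hw) if (length(centers))
    GRanges("chr1", IRanges(centers - hw, centers + hw))
    else GRanges()
  fdr1A <- c(mk(centersShared, 100L), mk(centersAonly, 100L))
  fdr1B <- c(mk(centersShared, 100L), mk(centersBonly, 100L))
  fdr25A <- c(mk(centersShared, 200L), mk(centersAonly, 200L))
  fdr25B <- c(mk(centersShared, 200L), mk(centersBonly, 200L))
  list(A = DualTierPeaks(factorName, "W", fdr1A, fdr25A),
       B = DualTierPeaks(factorName, "EA", fdr1B, fdr25B),
       nShared = nShared, nA = nA, nB = nB)
}

smallGeneratorConfig <- function(seed = 11) {
  generatorConfig(
    seed = seed, nChroms = 2L, chromLength = 700000L,
    nHubs = 40L, nGenes = 300L, catalogSize = 60L,
    factors = list(
      Sd = list(nPeaks = c(W = 100L, EA = 60L), sharedFraction = 0.5,
                pattern = "GGAATG"),
      Hth = list(nPeaks = c(W = 100L, EA = 60L), sharedFraction = 0.5,
                 pattern = "TGAY{N0-2}TGAY")))
}

# Lazily generated, memoized small bundle shared across test files.
.bundleCache <- new.env(parent = emptyenv())
smallBundleDir <- function() {
  if (is.null(.bundleCache$dir)) {
    dir <- file.path(tempdir(), "discchip-small-bundle")
    generateBundle(smallGeneratorConfig(), dir)
    .bundleCache$dir <- dir
  }
  .bundleCache$dir
}

# Tiny gene-model fixture: two genes on opposite strands.
toyGeneModels <- function() {
  bodies <- GRanges("chr1", IRanges(c(2001, 6001), c(3000, 7000)),
                    strand = c("+", "-"))
  exons <- GRangesList(
    GRanges("chr1", IRanges(c(2001, 2701), c(2300, 3000)), strand = "+"),
    GRanges("chr1", IRanges(c(6001, 6801), c(6200, 7000)), strand = "-"))
  discChIP:::makeGeneModels(bodies, c("gA", "gB"), exons)
}
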