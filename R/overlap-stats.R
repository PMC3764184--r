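#' Binned hypergeometric co-occurrence test between two interval sets
#'
#' The genome is tiled into fixed-width bins (the null-model unit). With
#' `N` bins in total, `n` bins hit by set A, `K` bins hit by set B and
#' `k` bins hit by both, the expected double-hit count under random
#' placement is `n*K/N` and the co-occurrence p-value is the upper
#' hypergeometric tail `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' A bin is "hit" when at least one interval of the set overlaps it.
#'
#' p-values are floored at the smallest positive double so that
#' `-ln(p)` stays finite.
#'
#' @param setA,setB `GRanges`.
#' @param assembly [GenomeAssembly-class] defining the binnable genome.
#' @param binWidth bin width in bases (default 1000).
#' @return A one-row data.frame: `observed` (double-hit bins), `expected`,
#'   `pValue`, `negLogP`, `obsExpRatio`, and the margins `nBins`,
#'   `binsA`, `binsB`. With an empty set, `pValue` is 1 and the ratio is
#'   `NaN` (with a warning).
#' @examples
#' asm <- GenomeAssembly(c(chr1 = 20000))
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5000))
#' cooccurrenceTest(a, a, asm, binWidth = 1000)
#' @export
cooccurrenceTest <- function(setA, setB, assembly, binWidth = 1000) {
  if (binWidth < 1) stop("binWidth must be >= 1")
  if (!length(chromSizes(assembly))) stop("empty assembly")
  bins <- genomeBins(assembly, binWidth)
  hitA <- IRanges::overlapsAny(bins, setA)
  hitB <- IRanges::overlapsAny(bins, setB)
  N <- length(bins); n <- sum(hitA); K <- sum(hitB)
  k <- sum(hitA & hitB)
  expected <- n * K / N
  if (n == 0L || K == 0L) {
    warning("empty bin set for one side; ratio undefined")
    p <- 1
    ratio <- NaN
  } else {
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)
    ratio <- k / expected
  }
  data.frame(observed = k, expected = expected, pValue = p,
             negLogP = -log(p), obsExpRatio = ratio,
             nBins = N, binsA = n, binsB = K)
}

# Fixed-width tiling of the assembly (last tile per chromosome clipped).
genomeBins <- function(assembly, binWidth) {
  cs <- chromSizes(assembly)
  GenomicRanges::tileGenome(cs, tilewidth = binWidth,
                            cut.last.tile.in.chrom = TRUE)
}

#' All-pairs co-occurrence matrix over labeled interval sets
#'
#' Runs [cooccurrenceTest()] for every ordered pair (rows = query set A,
#' columns = reference set B). Used to compare specificity classes
#' across factors (the shared-vs-shared block is expected to dominate
#' when shared events colocalize across factors).
#'
#' @param sets named list of `GRanges` (>= 2 sets).
#' @param assembly [GenomeAssembly-class].
#' @param binWidth bin width in bases.
#' @return Long data.frame with columns `setA`, `setB` and the
#'   [cooccurrenceTest()] fields.
#' @export
pairwiseCooccurrence <- function(sets, assembly, binWidth = 1000) {
  if (length(sets) < 2 || is.null(names(sets)))
    stop("need >= 2 named sets")
  grid <- expand.grid(setA = names(sets), setB = names(sets),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$setA != grid$setB, , drop = FALSE]
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    cooccurrenceTest(sets[[grid$setA[i]]], sets[[grid$setB[i]]],
                     assembly, binWidth)))
  cbind(grid, res, row.names = NULL)
}

#' Reshape a pairwise co-occurrence table into a -ln(p) matrix
#'
#' @param tab output of [pairwiseCooccurrence()].
#' @param value which column to spread (default `"negLogP"`).
#' @return Numeric matrix, rows = query sets, columns = reference sets,
#'   `NA` on the diagonal.
#' @export
cooccurrenceMatrix <- function(tab, value = "negLogP") {
  sets <- unique(c(tab$setA, tab$setB))
  m <- matrix(NA_real_, length(sets), length(sets),
              dimnames = list(sets, sets))
  m[cbind(tab$setA, tab$setB)] <- tab[[value]]
  m
}

#' Enhancer-catalog overlap summary
#'
#' A catalog fragment is "bound" when at least one call overlaps it
#' (fragments partially overlapping several peaks count once). For each
#' tissue activity flag the summary reports how many bound fragments are
#' active there, the active fraction of bound fragments, and an
#' observed/expected ratio where the expectation assumes binding is
#' independent of activity (`expected = bound * active/catalog`).
#' Partially overlapping bound fragments are additionally collapsed with
#' [mergeIntervals()] into unique CRMs.
#'
#' @param calls `GRanges` of binding events.
#' @param catalog enhancer catalog `GRanges` from [readEnhancerCatalog()].
#' @return List with `perTissue` (data.frame: `tissue`, `boundFragments`,
#'   `activeAndBound`, `fraction`, `expected`, `obsExp`),
#'   `boundFragments` (count) and `uniqueCRMs` (count after merging).
#'   With no bound fragment the fractions are `NaN`.
#' @export
summarizeEnhancerOverlap <- function(calls, catalog) {
  if (!length(catalog)) stop("empty enhancer catalog")
  mc <- GenomicRanges::mcols(catalog)
  if (!all(CATALOG_TISSUES %in% colnames(mc)))
    stop("catalog lacks activity flags")
  bound <- IRanges::overlapsAny(catalog, calls)
  nb <- sum(bound)
  perTissue <- do.call(rbind, lapply(CATALOG_TISSUES, function(tis) {
    act <- mc[[tis]]
    ab <- sum(bound & act)
    expected <- nb * sum(act) / length(catalog)
    data.frame(tissue = tis, boundFragments = nb, activeAndBound = ab,
               fraction = if (nb > 0) ab / nb else NaN,
               expected = expected,
               obsExp = if (expected > 0) ab / expected else NaN)
  }))
  uniq <- if (nb > 0) length(mergeIntervals(catalog[bound])) else 0L
  list(perTissue = perTissue, boundFragments = nb, uniqueCRMs = uniq)
}
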