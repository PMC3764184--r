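#' Merge partially overlapping intervals into a minimal disjoint set
#'
#' Single-linkage merge: any chain of pairwise-overlapping intervals
#' collapses to one interval covering their union. The output is sorted,
#' non-overlapping and position-set preserving. This is the operation used
#' to collapse partially overlapping enhancer fragments into unique CRMs.
#'
#' @param x a `GRanges`.
#' @return A sorted, disjoint `GRanges` covering exactly the same bases.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 6, 21), c(10, 15, 30)))
#' mergeIntervals(gr)
#' @export
mergeIntervals <- function(x) {
  GenomicRanges::reduce(BiocGenerics::sort(GenomicRanges::granges(x)),
                        ignore.strand = TRUE)
}

#' Do two intervals share at least one base?
#'
#' Overlap throughout the package means >= 1 shared base; abutting
#' intervals (BED `[0,10)` vs `[10,20)`) do not overlap.
#'
#' @param a,b `GRanges` (recycled elementwise like [GenomicRanges::pintersect]).
#' @return Logical vector.
#' @export
intervalsOverlap <- function(a, b) {
  overlapLength(a, b) > 0L
}

#' Number of shared bases between parallel intervals
#'
#' @param a,b parallel `GRanges`.
#' @return Integer vector of overlap lengths (0 when disjoint or on
#'   different chromosomes).
#' @export
overlapLength <- function(a, b) {
  if (length(a) != length(b))
    stop("a and b must be parallel")
  same <- as.character(GenomicRanges::seqnames(a)) ==
          as.character(GenomicRanges::seqnames(b))
  len <- pmax(0L, pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
                  pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L)
  len[!same] <- 0L
  len
}

#' Peak center positions
#'
#' The center of an interval spanning 0-based `[s0, e0)` is
#' `floor((s0 + e0)/2)`; even-width intervals take the left of the two
#' middle bases. Returned as 1-based width-1 `GRanges`.
#'
#' @param x a `GRanges`.
#' @return Width-1 `GRanges` at each interval's center (metadata kept).
#' @export
peakCenter <- function(x) {
  center1 <- floor((GenomicRanges::start(x) - 1L + GenomicRanges::end(x)) / 2) + 1L
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(x),
                                IRanges::IRanges(center1, width = 1L),
                                strand = GenomicRanges::strand(x))
  GenomicRanges::mcols(out) <- GenomicRanges::mcols(x)
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(x)
  out
}

# Validate a GRanges against an assembly: all seqnames declared and all
# coordinates within chromosome bounds.
validateAgainstAssembly <- function(x, assembly, what = "interval") {
  cs <- chromSizes(assembly)
  sn <- as.character(GenomicRanges::seqnames(x))
  bad <- !(sn %in% names(cs))
  if (any(bad))
    stop(sprintf("%s on undeclared chromosome '%s'", what, sn[which(bad)[1]]))
  over <- GenomicRanges::end(x) > cs[sn]
  if (any(over))
    stop(sprintf("%s %s:%d-%d extends beyond chromosome end (%d)",
                 what, sn[which(over)[1]],
                 GenomicRanges::start(x)[which(over)[1]],
                 GenomicRanges::end(x)[which(over)[1]],
                 cs[sn[which(over)[1]]]))
  invisible(TRUE)
}
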