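#' Dual-FDR-threshold tissue-specificity classification
#'
#' Implements the dual-threshold rule for calling a binding event
#' tissue-specific: a stringent (1% FDR) peak in the home tissue is
#' SPECIFIC when it overlaps no permissive (25% FDR) peak of the partner
#' tissue, and SHARED when it overlaps at least one. Using the permissive
#' tier on the partner side avoids calling a peak tissue-specific merely
#' because it fell just below the stringent threshold there. Each
#' tissue's stringent peaks are labeled independently, so every FDR1 peak
#' of both tissues receives exactly one label.
#'
#' @param setA,setB [DualTierPeaks-class] for the two tissues of the same
#'   factor (validity of each set already guarantees tier nesting).
#' @return Named list of two [SpecificityCalls-class] objects, one per
#'   tissue, names being the tissue labels.
#' @examples
#' a <- DualTierPeaks("Sd", "W",
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)),
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(81, 220)))
#' b <- DualTierPeaks("Sd", "EA",
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250)),
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250)))
#' classifySpecificity(a, b)
#' @export
classifySpecificity <- function(setA, setB) {
  if (peakFactor(setA) != peakFactor(setB))
    stop("mismatched factors: ", peakFactor(setA), " vs ", peakFactor(setB))
  if (peakTissue(setA) == peakTissue(setB))
    stop("both sets claim tissue ", peakTissue(setA))
  lab <- function(home, partner) {
    calls <- fdr1Peaks(home)
    shared <- IRanges::overlapsAny(calls, fdr25Peaks(partner))
    GenomicRanges::mcols(calls)$label <-
      ifelse(shared, "SHARED", "SPECIFIC")
    new("SpecificityCalls", factorName = peakFactor(home),
        homeTissue = peakTissue(home), partnerTissue = peakTissue(partner),
        calls = calls)
  }
  out <- list(lab(setA, setB), lab(setB, setA))
  stats::setNames(out, c(peakTissue(setA), peakTissue(setB)))
}

#' Per-tissue shared/specific counts
#'
#' @param calls result of [classifySpecificity()].
#' @return data.frame with one row per tissue: `tissue`, `shared`,
#'   `specific`, `total`.
#' @export
specificityCounts <- function(calls) {
  do.call(rbind, lapply(calls, function(x) {
    lab <- GenomicRanges::mcols(specificityCalls(x))$label
    data.frame(factorName = x@factorName, tissue = x@homeTissue,
               shared = sum(lab == "SHARED"),
               specific = sum(lab == "SPECIFIC"),
               total = length(lab), row.names = NULL)
  }))
}

#' Merged consensus of tissue-shared binding
#'
#' One region list for the shared (both-tissue) class: the union of the
#' SHARED-labeled stringent peaks from both tissues, collapsed with
#' [mergeIntervals()] so reciprocal calls of the same event count once.
#'
#' @param calls result of [classifySpecificity()] (list of two
#'   [SpecificityCalls-class]).
#' @return Disjoint `GRanges` of merged shared regions.
#' @export
sharedConsensus <- function(calls) {
  shared <- lapply(calls, sharedPeaks)
  allShared <- suppressWarnings(
    do.call(c, unname(lapply(shared, GenomicRanges::granges))))
  if (!length(allShared)) return(GenomicRanges::GRanges())
  mergeIntervals(allShared)
}
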