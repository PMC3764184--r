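#' Mean signal profile around peak centers
#'
#' For every offset in `-halfwidth ... +halfwidth` relative to each peak
#' center, the mean of the track value across peaks. Positions where the
#' track is missing (`NA`) or that fall off the chromosome are excluded
#' from that offset's mean, so each offset has its own contributing
#' count.
#'
#' @param peaks `GRanges`.
#' @param track per-chromosome signal list from [readSignalTrack()].
#' @param halfwidth window half-width in bases (default 500).
#' @return data.frame with `2*halfwidth + 1` rows: `offset`, `mean`
#'   (`NaN` when no peak contributes), `n`.
#' @export
profileScores <- function(peaks, track, halfwidth = 500) {
  offsets <- seq(-halfwidth, halfwidth)
  centers <- GenomicRanges::start(peakCenter(peaks))
  sn <- as.character(GenomicRanges::seqnames(peaks))
  sums <- numeric(length(offsets))
  ns <- integer(length(offsets))
  for (ch in unique(sn)) {
    r <- track[[ch]]
    if (is.null(r)) stop("no track data for chromosome ", ch)
    v <- as.numeric(r)  # decode once per chromosome
    for (ct in centers[sn == ch]) {
      pos <- ct + offsets
      inside <- pos >= 1L & pos <= length(v)
      val <- rep(NA_real_, length(offsets))
      val[inside] <- v[pos[inside]]
      ok <- !is.na(val)
      sums[ok] <- sums[ok] + val[ok]
      ns <- ns + ok
    }
  }
  data.frame(offset = offsets,
             mean = ifelse(ns > 0, sums / pmax(ns, 1L), NaN),
             n = ns)
}

#' Maximal runs of perfect identity of a minimum length
#'
#' Detects ultraconserved elements from a binary per-base identity track
#' (1 = base identical between the two species, 0 = not): maximal runs
#' of 1s at least `minLen` bases long.
#'
#' @param track per-chromosome binary signal list (values 0/1; `NA` is
#'   treated as non-identity).
#' @param minLen minimum run length in bases (default 50).
#' @return `GRanges` of qualifying runs.
#' @export
findPerfectRuns <- function(track, minLen = 50) {
  out <- lapply(names(track), function(ch) {
    r <- track[[ch]]
    vals <- S4Vectors::runValue(r)
    if (any(!is.na(vals) & !(vals %in% c(0, 1))))
      stop("identity track must be binary (0/1)")
    r[is.na(r)] <- 0
    ir <- IRanges::reduce(methods::as(r == 1, "IRanges"))
    ir <- ir[IRanges::width(ir) >= minLen]
    if (!length(ir)) GenomicRanges::GRanges()
    else GenomicRanges::GRanges(ch, ir)
  })
  suppressWarnings(do.call(c, out))
}

#' Fraction of peaks overlapping an ultraconserved element
#'
#' @param peaks `GRanges`.
#' @param uces `GRanges` of ultraconserved elements.
#' @return List: `fraction` (of peaks with >= 1 overlapping element),
#'   `hits`, `n`, `overlapsUce` (logical vector).
#' @export
uceOverlapFraction <- function(peaks, uces) {
  ov <- IRanges::overlapsAny(peaks, uces)
  list(fraction = if (length(ov)) mean(ov) else NaN,
       hits = sum(ov), n = length(ov), overlapsUce = ov)
}

#' Chromatin-state composition and enrichment of a peak set
#'
#' Each peak is assigned the chromatin state at its center (exclusive,
#' so state fractions sum to 1); a center falling in a segmentation gap
#' goes to an UNASSIGNED bucket with a warning. Per-state enrichment is
#' the binned hypergeometric co-occurrence of the peak set with that
#' state's segments ([cooccurrenceTest()]). An any-overlap counting mode
#' is available for the composition (a peak then counts once per state
#' it touches and fractions need not sum to 1).
#'
#' @param peaks `GRanges`.
#' @param segmentation `GRanges` with a `state` column
#'   ([readSegmentationBed()]).
#' @param assembly [GenomeAssembly-class].
#' @param binWidth bin width for the enrichment null (default 1000).
#' @param mode `"center"` (exclusive, default) or `"any"` (any overlap).
#' @return data.frame with one row per state (plus UNASSIGNED if
#'   needed): `state`, `peakCount`, `fraction`, `genomeShare`, `pValue`,
#'   `negLogP`.
#' @export
stateEnrichment <- function(peaks, segmentation, assembly,
                            binWidth = 1000, mode = c("center", "any")) {
  mode <- match.arg(mode)
  st <- GenomicRanges::mcols(segmentation)$state
  if (is.null(st)) stop("segmentation lacks a state column")
  if (mode == "center") {
    centers <- peakCenter(peaks)
    hit <- GenomicRanges::findOverlaps(centers, segmentation,
                                       ignore.strand = TRUE)
    assigned <- rep(NA_character_, length(peaks))
    assigned[S4Vectors::queryHits(hit)] <-
      as.character(st[S4Vectors::subjectHits(hit)])
    if (anyNA(assigned))
      warning(sum(is.na(assigned)),
              " peak center(s) in segmentation gaps -> UNASSIGNED")
    assigned[is.na(assigned)] <- "UNASSIGNED"
    counts <- table(factor(assigned,
                           levels = c(CHROMATIN_STATES, "UNASSIGNED")))
    if (counts[["UNASSIGNED"]] == 0)
      counts <- counts[CHROMATIN_STATES]
  } else {
    counts <- vapply(CHROMATIN_STATES, function(s)
      sum(IRanges::overlapsAny(peaks, segmentation[st == s])), 0L)
  }
  genomeShare <- vapply(names(counts), function(s) {
    if (s == "UNASSIGNED") return(NA_real_)
    sum(GenomicRanges::width(segmentation[st == s])) /
      sum(chromSizes(assembly))
  }, 0)
  enr <- lapply(names(counts), function(s) {
    if (s == "UNASSIGNED" || counts[[s]] == 0)
      return(c(pValue = 1, negLogP = 0))
    r <- cooccurrenceTest(peaks, segmentation[st == s], assembly, binWidth)
    c(pValue = r$pValue, negLogP = r$negLogP)
  })
  enr <- do.call(rbind, enr)
  data.frame(state = names(counts),
             peakCount = as.integer(counts),
             fraction = as.numeric(counts) / max(length(peaks), 1L),
             genomeShare = genomeShare,
             pValue = enr[, "pValue"], negLogP = enr[, "negLogP"],
             row.names = NULL)
}
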