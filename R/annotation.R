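REGION_LABELS <- c("PROMOTER", "EXON", "INTRON", "INTERGENIC")

#' Assign each peak a single genomic-region label
#'
#' The label is decided at the peak center so that labels are mutually
#' exclusive and region fractions sum to one. Precedence:
#' PROMOTER > EXON > INTRON > INTERGENIC. The promoter is the
#' strand-aware 1 kb window immediately upstream of a TSS (the window
#' excludes the TSS base itself); a center inside a transcript but in no
#' exon is intronic; anything else is intergenic.
#'
#' @param peaks `GRanges`.
#' @param models [GeneModels-class].
#' @param promoterWindow upstream window size in bases (default 1000).
#' @param assembly optional [GenomeAssembly-class] for coordinate
#'   validation.
#' @return Factor of region labels parallel to `peaks`.
#' @export
assignRegion <- function(peaks, models, promoterWindow = 1000,
                         assembly = NULL) {
  if (!is.null(assembly)) validateAgainstAssembly(peaks, assembly, "peak")
  centers <- peakCenter(peaks)
  GenomicRanges::strand(centers) <- "*"
  tss <- geneTss(models)
  prom <- GenomicRanges::promoters(tss, upstream = promoterWindow,
                                   downstream = 0)
  exons <- BiocGenerics::unlist(geneExons(models))
  bodies <- geneBodies(models)
  lab <- rep("INTERGENIC", length(centers))
  lab[IRanges::overlapsAny(centers, bodies, ignore.strand = TRUE)] <- "INTRON"
  lab[IRanges::overlapsAny(centers, exons, ignore.strand = TRUE)] <- "EXON"
  lab[IRanges::overlapsAny(centers, prom, ignore.strand = TRUE)] <- "PROMOTER"
  factor(lab, levels = REGION_LABELS)
}

#' Fraction of peaks per genomic-region label
#'
#' @inheritParams assignRegion
#' @return Named numeric vector over the four labels summing to 1.
#' @export
regionBreakdown <- function(peaks, models, promoterWindow = 1000) {
  if (!length(peaks)) stop("need >= 1 peak")
  lab <- assignRegion(peaks, models, promoterWindow)
  table(lab) / length(lab)
}

#' Assign labeled peaks to target genes and derive regulatory-logic classes
#'
#' A gene is targeted by a peak when the peak overlaps the gene body or
#' lies within `maxDistance` bases of its TSS; one peak may target
#' several genes. Each targeted gene is then classified from the
#' multiset of its peaks' specificity labels: `SHARED_ONLY` (all peaks
#' shared), `SPECIFIC_ONLY` (all specific) or `SHARED_PLUS_SPECIFIC`
#' (both kinds). These three classes partition the targeted genes
#' exactly.
#'
#' @param calls `GRanges` with a `label` column (`SHARED`/`SPECIFIC`),
#'   e.g. [specificityCalls()] output.
#' @param models [GeneModels-class].
#' @param maxDistance TSS distance cutoff in bases (default 10000).
#' @return data.frame with one row per targeted gene: `gene_id`,
#'   `nShared`, `nSpecific`, `logicClass`.
#' @export
assignTargets <- function(calls, models, maxDistance = 10000) {
  lab <- GenomicRanges::mcols(calls)$label
  if (length(calls) && is.null(lab))
    stop("calls must carry a 'label' metadata column")
  bodies <- geneBodies(models)
  tss <- geneTss(models)
  # "within maxDistance of the TSS" = the peak reaches a base at most
  # maxDistance away from the TSS position.
  tssWin <- suppressWarnings(GenomicRanges::resize(
    tss, width = 2L * maxDistance + 1L, fix = "center"))
  tssWin <- GenomicRanges::trim(GenomicRanges::GRanges(
    GenomicRanges::seqnames(tssWin),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(tssWin)),
                     GenomicRanges::end(tssWin))))
  hitBody <- GenomicRanges::findOverlaps(calls, bodies, ignore.strand = TRUE)
  hitTss <- GenomicRanges::findOverlaps(calls, tssWin, ignore.strand = TRUE)
  pairs <- unique(rbind(
    cbind(S4Vectors::queryHits(hitBody), S4Vectors::subjectHits(hitBody)),
    cbind(S4Vectors::queryHits(hitTss), S4Vectors::subjectHits(hitTss))))
  if (!nrow(pairs))
    return(data.frame(gene_id = character(0), nShared = integer(0),
                      nSpecific = integer(0), logicClass = character(0)))
  gid <- GenomicRanges::mcols(bodies)$gene_id[pairs[, 2]]
  plab <- lab[pairs[, 1]]
  agg <- stats::aggregate(cbind(nShared = plab == "SHARED",
                                nSpecific = plab == "SPECIFIC"),
                          by = list(gene_id = gid), FUN = sum)
  agg$logicClass <- ifelse(agg$nSpecific == 0, "SHARED_ONLY",
                    ifelse(agg$nShared == 0, "SPECIFIC_ONLY",
                           "SHARED_PLUS_SPECIFIC"))
  agg[order(agg$gene_id), , drop = FALSE]
}

#' Hypergeometric gene-set (GO-style) enrichment with BH correction
#'
#' For each set, the upper-tail hypergeometric probability of drawing at
#' least the observed number of set members when sampling `|list|` genes
#' from the universe without replacement; Benjamini-Hochberg FDR across
#' sets.
#'
#' @param geneList character vector of hit genes (must be a subset of
#'   `universe`).
#' @param universe character vector of all assayable genes.
#' @param sets named list of gene sets (e.g. [readGeneSets()]).
#' @return data.frame sorted by p-value: `setName`, `hits`, `setSize`
#'   (after restriction to the universe), `listSize`, `universeSize`,
#'   `pValue`, `bhFdr`.
#' @export
geneSetEnrichment <- function(geneList, universe, sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  geneList <- unique(geneList)
  if (!all(geneList %in% universe))
    stop("geneList contains genes outside the universe")
  N <- length(universe); n <- length(geneList)
  rows <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(geneList, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(setName = nm, hits = k, setSize = K, listSize = n,
               universeSize = N, pValue = p)
  }))
  rows$bhFdr <- stats::p.adjust(rows$pValue, method = "BH")
  rows[order(rows$pValue), , drop = FALSE]
}
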