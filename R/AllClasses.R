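#' @import methods
#' @importFrom GenomicRanges GRanges granges countOverlaps findOverlaps
#'   reduce promoters resize tileGenome pintersect distance width start end
#'   strand seqnames mcols mcols<- coverage GRangesList
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny slice
#' @importFrom S4Vectors queryHits subjectHits Rle runValue runLength
#'   DataFrame metadata metadata<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   keepSeqlevels
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement replaceAt subseq
#' @importFrom BiocGenerics sort unlist
#' @importFrom stats phyper pbinom fisher.test p.adjust setNames rbinom
#'   runif ks.test
#' @importFrom utils read.table write.table head tail packageVersion
NULL

# Five-state chromatin alphabet used throughout.
CHROMATIN_STATES <- c("YELLOW", "RED", "BLUE", "GREEN", "BLACK")

# Catalog tissues with per-fragment activity flags.
CATALOG_TISSUES <- c("eye", "antenna", "leg", "wing")

#' GenomeAssembly: chromosome sizes plus optional sequence
#'
#' Lightweight container tying together a named vector of chromosome
#' lengths and, optionally, the genome sequence as a
#' [Biostrings::DNAStringSet]. Every interval consumer in the package
#' validates coordinates against `chromSizes`; operations needing sequence
#' (motif scanning) require `sequence` to be present.
#'
#' @slot chromSizes named numeric vector of chromosome lengths (bases).
#' @slot sequence `DNAStringSet` with one entry per chromosome, or an
#'   empty set when only sizes are known.
#' @export
setClass("GenomeAssembly",
  representation(chromSizes = "numeric", sequence = "DNAStringSet"),
  prototype(chromSizes = numeric(0), sequence = Biostrings::DNAStringSet())
)

setValidity("GenomeAssembly", function(object) {
  cs <- object@chromSizes
  if (length(cs) && (is.null(names(cs)) || any(!nzchar(names(cs)))))
    return("chromSizes must be a named vector with non-empty names")
  if (length(cs) && any(cs < 1)) return("chromosome lengths must be >= 1")
  if (anyDuplicated(names(cs))) return("duplicated chromosome names")
  sq <- object@sequence
  if (length(sq)) {
    if (!all(names(sq) %in% names(cs)))
      return("sequence names not declared in chromSizes")
    if (!all(BiocGenerics::width(sq) == unname(cs[names(sq)])))
      return("sequence lengths disagree with chromSizes")
  }
  TRUE
})

#' Construct a GenomeAssembly
#'
#' @param chromSizes named numeric vector of chromosome lengths.
#' @param sequence optional `DNAStringSet` (names must match `chromSizes`).
#' @return A [GenomeAssembly-class] object.
#' @examples
#' asm <- GenomeAssembly(c(chr2L = 1e4, chrX = 5e3))
#' @export
GenomeAssembly <- function(chromSizes, sequence = Biostrings::DNAStringSet()) {
  if (is.null(names(chromSizes)))
    stop("chromSizes must be named")
  new("GenomeAssembly", chromSizes = chromSizes, sequence = sequence)
}

#' @describeIn GenomeAssembly-class chromosome sizes accessor
#' @param x a `GenomeAssembly`
#' @export
chromSizes <- function(x) x@chromSizes

#' @describeIn GenomeAssembly-class genome sequence accessor
#' @export
genomeSequence <- function(x) x@sequence

#' @describeIn GenomeAssembly-class TRUE when sequence is attached
#' @export
hasSequence <- function(x) length(x@sequence) > 0L

setMethod("show", "GenomeAssembly", function(object) {
  cat("GenomeAssembly with", length(object@chromSizes), "chromosome(s),",
      format(sum(object@chromSizes), big.mark = ","), "bp total;",
      if (hasSequence(object)) "sequence attached" else "sizes only", "\n")
})

#' DualTierPeaks: one tissue's peak calls at two FDR tiers
#'
#' Holds, for one factor in one tissue, the stringent calls (1% FDR) and
#' the permissive calls (25% FDR) used by the dual-threshold specificity
#' rule. Validity enforces the nesting contract: every stringent peak must
#' overlap at least one permissive peak, because the permissive tier is a
#' superset call set at a weaker threshold. Violations are reported (not
#' silently repaired) with the offending peak's coordinates.
#'
#' @slot factorName identifier of the ChIPped factor (e.g. "Sd").
#' @slot tissue tissue identifier (e.g. "W" or "EA").
#' @slot fdr1 `GRanges` of stringent (1% FDR) peaks; a numeric `score`
#'   metadata column is kept when present.
#' @slot fdr25 `GRanges` of permissive (25% FDR) peaks.
#' @export
setClass("DualTierPeaks",
  representation(factorName = "character", tissue = "character",
                 fdr1 = "GRanges", fdr25 = "GRanges"))

setValidity("DualTierPeaks", function(object) {
  if (length(object@factorName) != 1L || !nzchar(object@factorName))
    return("factorName must be a single non-empty string")
  if (length(object@tissue) != 1L || !nzchar(object@tissue))
    return("tissue must be a single non-empty string")
  orphan <- !IRanges::overlapsAny(object@fdr1, object@fdr25)
  if (any(orphan)) {
    off <- object@fdr1[which(orphan)[1L]]
    return(sprintf(
      "nesting violation: FDR1 peak %s:%d-%d overlaps no FDR25 peak",
      as.character(GenomicRanges::seqnames(off)),
      GenomicRanges::start(off), GenomicRanges::end(off)))
  }
  TRUE
})

#' Construct a DualTierPeaks object
#'
#' @param factorName,tissue identifiers shared by both tiers.
#' @param fdr1,fdr25 `GRanges` of peaks at the stringent and permissive
#'   tier respectively.
#' @return A [DualTierPeaks-class] object; errors if any FDR1 peak fails
#'   the nesting contract.
#' @export
DualTierPeaks <- function(factorName, tissue, fdr1, fdr25) {
  new("DualTierPeaks", factorName = factorName, tissue = tissue,
      fdr1 = fdr1, fdr25 = fdr25)
}

#' @describeIn DualTierPeaks-class stringent-tier peaks
#' @param x a `DualTierPeaks`
#' @export
fdr1Peaks <- function(x) x@fdr1

#' @describeIn DualTierPeaks-class permissive-tier peaks
#' @export
fdr25Peaks <- function(x) x@fdr25

#' @describeIn DualTierPeaks-class tissue label
#' @export
peakTissue <- function(x) x@tissue

#' @describeIn DualTierPeaks-class factor label
#' @export
peakFactor <- function(x) x@factorName

setMethod("show", "DualTierPeaks", function(object) {
  cat("DualTierPeaks:", object@factorName, "in", object@tissue, "-",
      length(object@fdr1), "FDR1 peaks,", length(object@fdr25),
      "FDR25 peaks\n")
})

#' SpecificityCalls: labeled stringent peaks of one tissue
#'
#' The result of the dual-threshold rule for one factor and one home
#' tissue: each stringent (FDR1) peak of the home tissue labeled
#' `"SHARED"` (it overlaps at least one permissive FDR25 peak of the
#' partner tissue) or `"SPECIFIC"` (it overlaps none).
#'
#' @slot factorName,homeTissue,partnerTissue identifiers.
#' @slot calls `GRanges` with a `label` metadata column in
#'   `c("SHARED","SPECIFIC")` (plus any columns carried by the input).
#' @export
setClass("SpecificityCalls",
  representation(factorName = "character", homeTissue = "character",
                 partnerTissue = "character", calls = "GRanges"))

setValidity("SpecificityCalls", function(object) {
  lab <- GenomicRanges::mcols(object@calls)$label
  if (length(object@calls) && is.null(lab))
    return("calls must carry a 'label' metadata column")
  if (length(object@calls) && !all(lab %in% c("SHARED", "SPECIFIC")))
    return("labels must be SHARED or SPECIFIC")
  TRUE
})

#' @describeIn SpecificityCalls-class labeled peaks as GRanges
#' @param x a `SpecificityCalls`
#' @export
specificityCalls <- function(x) x@calls

#' @describeIn SpecificityCalls-class SHARED-labeled subset
#' @export
sharedPeaks <- function(x) x@calls[GenomicRanges::mcols(x@calls)$label == "SHARED"]

#' @describeIn SpecificityCalls-class SPECIFIC-labeled subset
#' @export
specificPeaks <- function(x) x@calls[GenomicRanges::mcols(x@calls)$label == "SPECIFIC"]

setMethod("show", "SpecificityCalls", function(object) {
  lab <- GenomicRanges::mcols(object@calls)$label
  cat("SpecificityCalls:", object@factorName, "in", object@homeTissue,
      "(vs", paste0(object@partnerTissue, "):"),
      sum(lab == "SHARED"), "shared,", sum(lab == "SPECIFIC"),
      "specific\n")
})

#' GeneModels: transcript models with strand-aware TSS
#'
#' @slot genes `GRanges` of transcript bodies with metadata columns
#'   `gene_id` and `tss` (1-based position; equals `start` on `+`,
#'   `end` on `-`).
#' @slot exons `GRangesList` parallel to `genes`.
#' @export
setClass("GeneModels",
  representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
  if (length(object@genes) != length(object@exons))
    return("genes and exons must be parallel")
  mc <- GenomicRanges::mcols(object@genes)
  if (length(object@genes) && (is.null(mc$gene_id) || is.null(mc$tss)))
    return("genes need gene_id and tss metadata columns")
  if (length(object@genes)) {
    plus <- as.character(GenomicRanges::strand(object@genes)) == "+"
    okp <- mc$tss[plus] == GenomicRanges::start(object@genes)[plus]
    okm <- mc$tss[!plus] == GenomicRanges::end(object@genes)[!plus]
    if (!all(c(okp, okm)))
      return("tss must equal start on + strand and end on - strand")
  }
  TRUE
})

#' @describeIn GeneModels-class transcript bodies
#' @param x a `GeneModels`
#' @export
geneBodies <- function(x) x@genes

#' @describeIn GeneModels-class exon ranges, parallel to [geneBodies()]
#' @export
geneExons <- function(x) x@exons

#' @describeIn GeneModels-class TSS positions as width-1 GRanges
#' @export
geneTss <- function(x) {
  g <- x@genes
  GenomicRanges::GRanges(GenomicRanges::seqnames(g),
    IRanges::IRanges(GenomicRanges::mcols(g)$tss, width = 1L),
    strand = GenomicRanges::strand(g),
    gene_id = GenomicRanges::mcols(g)$gene_id)
}

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", length(object@genes), "transcript(s)\n")
})

#' IUPACPattern: degenerate consensus, optionally a spaced dimer
#'
#' A binding-site consensus over the IUPAC nucleotide alphabet. A monomer
#' has only `halfSite1`; a spaced dimer has two half-sites separated by an
#' unconstrained spacer whose length ranges over
#' `spacerMin:spacerMax` (e.g. `TGAY{N0-2}TGAY`).
#'
#' @slot name pattern label.
#' @slot halfSite1,halfSite2 IUPAC strings (`halfSite2` empty for
#'   monomers).
#' @slot spacerMin,spacerMax admissible spacer lengths in bases.
#' @export
setClass("IUPACPattern",
  representation(name = "character", halfSite1 = "character",
                 halfSite2 = "character", spacerMin = "integer",
                 spacerMax = "integer"))

setValidity("IUPACPattern", function(object) {
  ok <- function(s) all(strsplit(s, "")[[1]] %in% names(IUPAC_SETS))
  if (!nzchar(object@halfSite1) || !ok(object@halfSite1))
    return("halfSite1 must be a non-empty IUPAC string")
  if (nzchar(object@halfSite2) && !ok(object@halfSite2))
    return("halfSite2 contains a non-IUPAC symbol")
  if (object@spacerMin < 0L || object@spacerMin > object@spacerMax)
    return("need 0 <= spacerMin <= spacerMax")
  TRUE
})

#' Construct an IUPACPattern
#'
#' @param halfSite1 IUPAC consensus of the (first) half-site.
#' @param halfSite2 optional second half-site for spaced dimers.
#' @param spacerMin,spacerMax admissible spacer lengths (ignored for
#'   monomers).
#' @param name label; defaults to a compact rendering of the pattern.
#' @return An [IUPACPattern-class] object.
#' @examples
#' sdMotif  <- IUPACPattern("GGAATG", name = "Sd")
#' dimer    <- IUPACPattern("TGAY", "TGAY", 0, 2, name = "Hth-Exd")
#' @export
IUPACPattern <- function(halfSite1, halfSite2 = "", spacerMin = 0,
                         spacerMax = 0, name = NULL) {
  halfSite1 <- toupper(halfSite1); halfSite2 <- toupper(halfSite2)
  if (is.null(name)) {
    name <- if (nzchar(halfSite2))
      sprintf("%s{N%d-%d}%s", halfSite1, spacerMin, spacerMax, halfSite2)
    else halfSite1
  }
  new("IUPACPattern", name = name, halfSite1 = halfSite1,
      halfSite2 = halfSite2, spacerMin = as.integer(spacerMin),
      spacerMax = as.integer(spacerMax))
}

#' @describeIn IUPACPattern-class TRUE for spaced dimers
#' @param x an `IUPACPattern`
#' @export
isDimer <- function(x) nzchar(x@halfSite2)

#' @describeIn IUPACPattern-class shortest concrete match length
#' @export
patternMinWidth <- function(x) {
  nchar(x@halfSite1) +
    if (isDimer(x)) x@spacerMin + nchar(x@halfSite2) else 0L
}

setMethod("show", "IUPACPattern", function(object) {
  cat("IUPACPattern", object@name, "\n")
})
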