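#' Read a BED file of peaks or plain intervals
#'
#' BED3/5/6 input (0-based half-open on disk, converted to the package's
#' 1-based `GRanges` on read). Track and comment lines are skipped; record
#' order is preserved. When `factorName`, `tissue` or `fdrTier` are given
#' (a peak file holds one factor/tissue/tier) they are attached as
#' metadata columns.
#'
#' @param path BED file.
#' @param factorName,tissue optional identifiers attached to every record.
#' @param fdrTier optional FDR tier of the calls; must be 1 or 25.
#' @param assembly optional [GenomeAssembly-class]; when given,
#'   coordinates are validated against it.
#' @return `GRanges` with whatever of `name`, `score`, `factorName`,
#'   `tissue`, `fdrTier` apply.
#' @export
readPeaksBed <- function(path, factorName = NULL, tissue = NULL,
                         fdrTier = NULL, assembly = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  gr <- methods::as(gr, "GRanges")
  if (any(GenomicRanges::width(gr) < 1L))
    stop("validation error in ", path, ": interval with start >= end")
  if (!is.null(fdrTier)) {
    if (!fdrTier %in% c(1, 25)) stop("fdrTier must be 1 or 25")
    GenomicRanges::mcols(gr)$fdrTier <- as.integer(fdrTier)
  }
  if (!is.null(factorName)) GenomicRanges::mcols(gr)$factorName <- factorName
  if (!is.null(tissue)) GenomicRanges::mcols(gr)$tissue <- tissue
  sc <- GenomicRanges::mcols(gr)$score
  if (!is.null(sc) && any(!is.finite(sc)))
    stop("non-finite score in ", path)
  if (!is.null(assembly)) validateAgainstAssembly(gr, assembly, "peak")
  gr
}

#' Write intervals to BED
#'
#' Inverse of [readPeaksBed()]: `read(write(x))` reproduces coordinates,
#' name and score field-for-field. A `label` metadata column (specificity
#' calls) is written into the BED name field when no `name` is present.
#'
#' @param x `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeaksBed <- function(x, path) {
  x <- GenomicRanges::granges(x, use.mcols = TRUE)
  mc <- GenomicRanges::mcols(x)
  if (is.null(mc$name) && !is.null(mc$label))
    GenomicRanges::mcols(x)$name <- mc$label
  keep <- intersect(c("name", "score"), colnames(GenomicRanges::mcols(x)))
  GenomicRanges::mcols(x) <- GenomicRanges::mcols(x)[, keep, drop = FALSE]
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}

#' Read a five-state chromatin segmentation from BED4
#'
#' State label is taken from the BED name field and must be one of
#' YELLOW, RED, BLUE, GREEN, BLACK. Intervals must be non-overlapping.
#'
#' @param path BED file with the state in column 4.
#' @return `GRanges` with a `state` factor metadata column.
#' @export
readSegmentationBed <- function(path) {
  gr <- readPeaksBed(path)
  st <- GenomicRanges::mcols(gr)$name
  if (is.null(st)) stop("segmentation BED needs the state in column 4")
  bad <- !(st %in% CHROMATIN_STATES)
  if (any(bad))
    stop("unknown chromatin state label: ", st[which(bad)[1]])
  if (!GenomicRanges::isDisjoint(gr))
    stop("segmentation intervals overlap")
  GenomicRanges::mcols(gr) <- NULL
  GenomicRanges::mcols(gr)$state <- factor(st, levels = CHROMATIN_STATES)
  gr
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3: one model per `mRNA`/`transcript` feature (falling back to
#' `gene` features when no transcripts exist), with exons attached via
#' their `Parent`; an exon whose Parent is unknown is an error. BED12:
#' one model per line, blocks becoming exons. The TSS is derived from
#' strand: the transcript's lowest coordinate on `+`, highest on `-`.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return A [GeneModels-class] object.
#' @export
readGeneModels <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed12"
  if (format == "gff3") readGeneModelsGff3(path) else readGeneModelsBed12(path)
}

readGeneModelsGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(GenomicRanges::mcols(gr)$type)
  tx <- gr[ty %in% c("mRNA", "transcript")]
  if (!length(tx)) tx <- gr[ty == "gene"]
  if (!length(tx)) stop("no gene/mRNA features in ", path)
  txid <- GenomicRanges::mcols(tx)$ID
  if (is.null(txid) || any(is.na(txid)))
    stop("transcripts in ", path, " lack ID attributes")
  ex <- gr[ty == "exon"]
  exl <- rep(list(NULL), length(tx))
  if (length(ex)) {
    par <- as.character(unlist(GenomicRanges::mcols(ex)$Parent))
    if (length(par) != length(ex))
      stop("exon without a single Parent in ", path)
    bad <- !(par %in% txid)
    if (any(bad)) stop("orphan exon (unknown Parent '",
                       par[which(bad)[1]], "') in ", path)
    idx <- split(seq_along(ex), factor(par, levels = txid))
    exl <- lapply(idx, function(i) GenomicRanges::granges(ex[i]))
  }
  exl <- lapply(seq_along(tx), function(i) {
    e <- exl[[i]]
    if (is.null(e) || !length(e)) GenomicRanges::granges(tx[i]) else e
  })
  makeGeneModels(GenomicRanges::granges(tx), txid,
                 GenomicRanges::GRangesList(exl))
}

readGeneModelsBed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(GenomicRanges::mcols(gr)$blocks))
    stop(path, " is not BED12 (no block columns)")
  nm <- GenomicRanges::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("tx", seq_along(gr))
  bl <- GenomicRanges::mcols(gr)$blocks  # block ranges relative to start
  exl <- lapply(seq_along(gr), function(i) {
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[i],
      IRanges::shift(bl[[i]], GenomicRanges::start(gr)[i] - 1L),
      strand = GenomicRanges::strand(gr)[i])
  })
  makeGeneModels(GenomicRanges::granges(gr), nm,
                 GenomicRanges::GRangesList(exl))
}

makeGeneModels <- function(bodies, ids, exons) {
  st <- as.character(GenomicRanges::strand(bodies))
  if (any(st == "*"))
    st[st == "*"] <- "+"  # unstranded models read as +
  GenomicRanges::strand(bodies) <- st
  GenomicRanges::mcols(bodies)$gene_id <- as.character(ids)
  GenomicRanges::mcols(bodies)$tss <- ifelse(st == "+",
    GenomicRanges::start(bodies), GenomicRanges::end(bodies))
  new("GeneModels", genes = bodies, exons = exons)
}

#' Write gene models to GFF3
#'
#' @param models a [GeneModels-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGff3 <- function(models, path) {
  g <- geneBodies(models)
  ex <- geneExons(models)
  tx <- GenomicRanges::granges(g)
  GenomicRanges::mcols(tx)$type <- "mRNA"
  GenomicRanges::mcols(tx)$ID <- GenomicRanges::mcols(g)$gene_id
  exu <- BiocGenerics::unlist(ex)
  GenomicRanges::mcols(exu)$type <- "exon"
  GenomicRanges::mcols(exu)$Parent <- rep(GenomicRanges::mcols(g)$gene_id,
                                          lengths(ex))
  rtracklayer::export(c(tx, exu), path, format = "gff3")
  invisible(path)
}

#' Read a genome FASTA into a GenomeAssembly
#'
#' @param path FASTA file.
#' @return [GenomeAssembly-class] with sequence attached.
#' @export
readGenomeFasta <- function(path) {
  sq <- Biostrings::readDNAStringSet(path)
  names(sq) <- sub("\\s.*$", "", names(sq))
  GenomeAssembly(stats::setNames(BiocGenerics::width(sq), names(sq)), sq)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chrom, length.
#' @return [GenomeAssembly-class] (sizes only).
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           stringsAsFactors = FALSE)
  GenomeAssembly(stats::setNames(as.numeric(tab$length), tab$chrom))
}

#' Write chromosome sizes
#' @param assembly a [GenomeAssembly-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeChromSizes <- function(assembly, path) {
  cs <- chromSizes(assembly)
  utils::write.table(data.frame(names(cs), as.integer(cs)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a per-base signal track (bedGraph or wiggle)
#'
#' Returns one run-length vector per chromosome, padded with `NA` where
#' the track has no data: gaps are missing, never zero.
#'
#' @param path bedGraph (`.bedgraph`, `.bg`) or wiggle (`.wig`) file.
#' @param assembly [GenomeAssembly-class] giving chromosome bounds.
#' @return Named list of [S4Vectors::Rle] vectors, one per chromosome,
#'   each of the chromosome's length.
#' @export
readSignalTrack <- function(path, assembly) {
  fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "WIG" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  if (any(!is.finite(GenomicRanges::mcols(gr)$score)))
    stop("non-finite value in signal track ", path)
  validateAgainstAssembly(gr, assembly, "track interval")
  signalToRleList(gr, assembly)
}

# GRanges with score -> per-chromosome Rle with NA gaps.
signalToRleList <- function(gr, assembly) {
  cs <- chromSizes(assembly)
  out <- lapply(names(cs), function(ch) {
    v <- S4Vectors::Rle(NA_real_, cs[[ch]])
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    if (length(g)) {
      g <- BiocGenerics::sort(g)
      v[IRanges::IRanges(GenomicRanges::start(g), GenomicRanges::end(g))] <-
        rep(GenomicRanges::mcols(g)$score, GenomicRanges::width(g))
    }
    v
  })
  stats::setNames(out, names(cs))
}

#' Write a signal track as bedGraph
#'
#' `NA` stretches are omitted (gaps mean missing data).
#'
#' @param track named list of per-chromosome `Rle` (see [readSignalTrack()]).
#' @param path output bedGraph.
#' @return `path`, invisibly.
#' @export
writeSignalTrack <- function(track, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ch in names(track)) {
    r <- track[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    vals <- S4Vectors::runValue(r)
    keep <- !is.na(vals)
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep] - 1L,
                         ends[keep], vals[keep]), con)
  }
  invisible(path)
}

#' Read an enhancer catalog TSV
#'
#' Expected columns: `id`, `chrom`, `start`, `end` (0-based half-open on
#' disk) and one 0/1 activity flag per tissue (`eye`, `antenna`, `leg`,
#' `wing`).
#'
#' @param path TSV with a header line.
#' @return `GRanges` with `id` plus logical activity columns.
#' @export
readEnhancerCatalog <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", CATALOG_TISSUES)
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("enhancer catalog missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$id)) stop("duplicated fragment id in catalog")
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1L, tab$end))
  GenomicRanges::mcols(gr)$id <- tab$id
  for (tis in CATALOG_TISSUES)
    GenomicRanges::mcols(gr)[[tis]] <- tab[[tis]] != 0
  gr
}

#' Write an enhancer catalog TSV
#' @param catalog `GRanges` as returned by [readEnhancerCatalog()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeEnhancerCatalog <- function(catalog, path) {
  mc <- GenomicRanges::mcols(catalog)
  tab <- data.frame(id = mc$id,
                    chrom = as.character(GenomicRanges::seqnames(catalog)),
                    start = GenomicRanges::start(catalog) - 1L,
                    end = GenomicRanges::end(catalog))
  for (tis in CATALOG_TISSUES) tab[[tis]] <- as.integer(mc[[tis]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' @param path GMT file (set name, description, then gene ids).
#' @return Named list of character vectors.
#' @export
readGeneSets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0)) stop("empty gene set in ", path)
  sets
}

#' Write a GMT gene-set library
#' @param sets named list of character vectors.
#' @param path output GMT.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(sets, path) {
  writeLines(vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), ""), path)
  invisible(path)
}
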