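#' Build and validate a pipeline run configuration
#'
#' Collects input paths and tunable parameters for [runAll()]. Optional
#' inputs may be `NULL`; the corresponding stage is then skipped with an
#' explicit notice, never silently. Referenced files must exist at
#' validation time.
#'
#' @param peakFiles nested list `factor -> tissue -> c(fdr1=, fdr25=)` of
#'   BED paths.
#' @param chromSizes chromosome-sizes TSV (required).
#' @param genome optional genome FASTA (motif stage).
#' @param genes optional gene-model GFF3/BED12 (annotation stage).
#' @param segmentation optional five-state BED (chromatin stage).
#' @param conservation optional bedGraph/wiggle (conservation stage).
#' @param uce optional ultraconserved-element BED.
#' @param enhancers optional enhancer-catalog TSV.
#' @param geneSets optional GMT library.
#' @param motifs optional consensus motif list, `factor -> pattern
#'   string` (or a file from [writeConsensusMotifs()] whose names match
#'   factors).
#' @param binWidth,promoterWindow,maxDistance,profileHalfwidth,eThreshold
#'   analysis parameters (defaults 1000, 1000, 10000, 500, 10).
#' @param outDir output directory for stage TSV/JSON files.
#' @return A list of class `"discChIPRunConfig"`.
#' @export
runConfig <- function(peakFiles, chromSizes, genome = NULL, genes = NULL,
                      segmentation = NULL, conservation = NULL, uce = NULL,
                      enhancers = NULL, geneSets = NULL, motifs = NULL,
                      binWidth = 1000, promoterWindow = 1000,
                      maxDistance = 10000, profileHalfwidth = 500,
                      eThreshold = 10, outDir = ".") {
  cfg <- list(peakFiles = peakFiles, chromSizes = chromSizes,
              genome = genome, genes = genes, segmentation = segmentation,
              conservation = conservation, uce = uce,
              enhancers = enhancers, geneSets = geneSets, motifs = motifs,
              binWidth = binWidth, promoterWindow = promoterWindow,
              maxDistance = maxDistance,
              profileHalfwidth = profileHalfwidth,
              eThreshold = eThreshold, outDir = outDir)
  for (p in c(unlist(peakFiles), chromSizes, genome, genes, segmentation,
              conservation, uce, enhancers, geneSets))
    if (is.character(p) && !file.exists(p)) stop("missing input file: ", p)
  class(cfg) <- "discChIPRunConfig"
  cfg
}

#' Point a run configuration at a generated bundle directory
#'
#' @param dir directory written by [generateBundle()].
#' @param ... parameter overrides passed to [runConfig()].
#' @return A `"discChIPRunConfig"` list.
#' @export
bundleRunConfig <- function(dir, ...) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tis <- man$tissues
  peakFiles <- lapply(stats::setNames(names(man$factors),
                                      names(man$factors)), function(f)
    lapply(stats::setNames(tis, tis), function(t)
      c(fdr1 = file.path(dir, sprintf("%s_%s_fdr1.bed", f, t)),
        fdr25 = file.path(dir, sprintf("%s_%s_fdr25.bed", f, t)))))
  motifs <- lapply(man$factors, function(x)
    if (is.null(x$pattern) || is.na(x$pattern)) NULL else x$pattern)
  motifs <- motifs[!vapply(motifs, is.null, logical(1))]
  runConfig(peakFiles,
            chromSizes = file.path(dir, "chrom.sizes"),
            genome = file.path(dir, "genome.fa"),
            genes = file.path(dir, "genes.gff3"),
            segmentation = file.path(dir, "segmentation.bed"),
            conservation = file.path(dir, "conservation.bedGraph"),
            uce = file.path(dir, "uce.bed"),
            enhancers = file.path(dir, "enhancers.tsv"),
            geneSets = file.path(dir, "genesets.gmt"),
            motifs = motifs, ...)
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full tissue-context analysis
#'
#' Executes, in dependency order: specificity classification per factor;
#' pairwise class co-occurrence; genomic-region breakdown; target-gene
#' logic partition and gene-set enrichment; motif-containment fractions
#' with a chromatin-state contrast; conservation profiles,
#' ultraconserved-element overlap and chromatin-state enrichment; and
#' the enhancer-catalog summary. Stage outputs are written as plain TSV
#' under `config$outDir` plus a JSON report; with fixed inputs and
#' configuration a rerun is byte-identical (the analysis draws no random
#' numbers and the report carries no wall-clock state). Stages whose
#' optional inputs are absent are skipped with a notice in
#' `report$skipped`.
#'
#' @param config a [runConfig()] list.
#' @param verbose emit per-stage messages (default TRUE).
#' @return The run report (list), invisibly also written to
#'   `report.json`.
#' @export
runAll <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "discChIPRunConfig"))
  cfg <- config
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[discChIP] ", ...)
  report <- list(
    parameters = cfg[c("binWidth", "promoterWindow", "maxDistance",
                       "profileHalfwidth", "eThreshold")],
    provenance = list(
      package = as.character(utils::packageVersion("discChIP")),
      configHash = digestConfig(cfg)),
    skipped = character(0))
  say("defaults in effect: binWidth=", cfg$binWidth, " promoterWindow=",
      cfg$promoterWindow, " maxDistance=", cfg$maxDistance,
      " profileHalfwidth=", cfg$profileHalfwidth,
      " eThreshold=", cfg$eThreshold)

  assembly <- readChromSizes(cfg$chromSizes)
  tissues <- names(cfg$peakFiles[[1]])

  ## stage: classify
  say("stage classify")
  calls <- list(); classSets <- list()
  countsTab <- list()
  for (f in names(cfg$peakFiles)) {
    pf <- cfg$peakFiles[[f]]
    sets <- lapply(tissues, function(t)
      DualTierPeaks(f, t,
        readPeaksBed(pf[[t]][["fdr1"]], factorName = f, tissue = t,
                     fdrTier = 1, assembly = assembly),
        readPeaksBed(pf[[t]][["fdr25"]], factorName = f, tissue = t,
                     fdrTier = 25, assembly = assembly)))
    cl <- classifySpecificity(sets[[1]], sets[[2]])
    calls[[f]] <- cl
    countsTab[[f]] <- specificityCounts(cl)
    classSets[[paste0(f, "_shared")]] <- sharedConsensus(cl)
    for (t in tissues) {
      sp <- specificPeaks(cl[[t]])
      classSets[[sprintf("%s_%s_specific", f, t)]] <- sp
      writePeaksBed(specificityCalls(cl[[t]]),
                    file.path(cfg$outDir, sprintf("calls_%s_%s.bed", f, t)))
    }
  }
  report$classify <- do.call(rbind, c(countsTab, list(make.row.names = FALSE)))
  writeTsv(report$classify, file.path(cfg$outDir, "classify_counts.tsv"))

  ## stage: overlap matrices
  say("stage overlap")
  nonEmpty <- classSets[vapply(classSets, length, 0L) > 0]
  if (length(nonEmpty) >= 2) {
    ov <- pairwiseCooccurrence(nonEmpty, assembly, cfg$binWidth)
    writeTsv(ov, file.path(cfg$outDir, "class_cooccurrence.tsv"))
    report$overlapTopPair <- ov[which.max(ov$negLogP),
                                c("setA", "setB", "negLogP")]
  }

  ## stage: annotation
  if (is.null(cfg$genes)) {
    report$skipped <- c(report$skipped,
                        "annotation: no gene models supplied")
    say("stage annotation SKIPPED (no gene models)")
  } else {
    say("stage annotation")
    models <- readGeneModels(cfg$genes)
    rb <- list()
    for (nm in names(nonEmpty))
      rb[[nm]] <- as.numeric(regionBreakdown(nonEmpty[[nm]], models,
                                             cfg$promoterWindow))
    breakdown <- data.frame(set = names(rb),
                            do.call(rbind, rb))
    colnames(breakdown)[-1] <- REGION_LABELS
    report$regionBreakdown <- breakdown
    writeTsv(breakdown, file.path(cfg$outDir, "region_breakdown.tsv"))

    logic <- list()
    for (f in names(calls)) {
      allCalls <- suppressWarnings(do.call(c,
        unname(lapply(calls[[f]], function(x) {
          g <- specificityCalls(x)
          GenomicRanges::mcols(g) <-
            GenomicRanges::mcols(g)[, "label", drop = FALSE]
          g
        }))))
      tg <- assignTargets(allCalls, models, cfg$maxDistance)
      logic[[f]] <- tg
      writeTsv(tg, file.path(cfg$outDir, sprintf("gene_logic_%s.tsv", f)))
      if (!is.null(cfg$geneSets)) {
        sets <- readGeneSets(cfg$geneSets)
        universe <- GenomicRanges::mcols(geneBodies(models))$gene_id
        sharedOnly <- tg$gene_id[tg$logicClass == "SHARED_ONLY"]
        if (length(sharedOnly)) {
          enr <- geneSetEnrichment(sharedOnly, universe, sets)
          writeTsv(enr, file.path(cfg$outDir,
                                  sprintf("enrichment_%s_shared_only.tsv", f)))
        }
      }
    }
    report$geneLogic <- stats::setNames(lapply(logic, function(tg)
      as.list(table(tg$logicClass))), names(logic))
  }

  ## stage: motifs
  if (is.null(cfg$genome) || is.null(cfg$motifs) || !length(cfg$motifs)) {
    report$skipped <- c(report$skipped, "motifs: no genome or motif list")
    say("stage motifs SKIPPED")
  } else {
    say("stage motifs")
    asmSeq <- readGenomeFasta(cfg$genome)
    seg <- if (!is.null(cfg$segmentation))
      readSegmentationBed(cfg$segmentation) else NULL
    motifRows <- list()
    for (f in intersect(names(cfg$motifs), names(calls))) {
      pattern <- parsePatternString(cfg$motifs[[f]])
      for (nm in grep(paste0("^", f, "_"), names(nonEmpty), value = TRUE)) {
        mf <- peakMotifFraction(nonEmpty[[nm]], asmSeq, pattern)
        row <- data.frame(set = nm, motif = pattern@name, hits = mf$hits,
                          n = mf$n, fraction = mf$fraction)
        if (!is.null(seg)) {
          st <- centerState(nonEmpty[[nm]], seg)
          for (s in c("BLUE", "YELLOW", "RED")) {
            sel <- st == s
            row[[paste0("frac_", s)]] <-
              if (any(sel)) mean(mf$hasMotif[sel]) else NaN
            row[[paste0("n_", s)]] <- sum(sel)
          }
          blue <- st == "BLUE"; yellow <- st == "YELLOW"
          row$pBlueVsYellow <- if (any(blue) && any(yellow))
            compareFractions(sum(mf$hasMotif[blue]), sum(blue),
                             sum(mf$hasMotif[yellow]), sum(yellow)) else NA
        }
        motifRows[[length(motifRows) + 1L]] <- row
      }
    }
    report$motifFractions <- do.call(rbind, motifRows)
    writeTsv(report$motifFractions,
             file.path(cfg$outDir, "motif_fractions.tsv"))
  }

  ## stage: conservation / chromatin context
  if (is.null(cfg$conservation) && is.null(cfg$segmentation)) {
    report$skipped <- c(report$skipped,
                        "context: no conservation track or segmentation")
    say("stage context SKIPPED")
  } else {
    say("stage context")
    if (!is.null(cfg$conservation)) {
      track <- readSignalTrack(cfg$conservation, assembly)
      prof <- list()
      for (nm in names(nonEmpty)) {
        pr <- profileScores(nonEmpty[[nm]], track, cfg$profileHalfwidth)
        pr$set <- nm
        prof[[nm]] <- pr
      }
      profAll <- do.call(rbind, c(prof, list(make.row.names = FALSE)))
      writeTsv(profAll, file.path(cfg$outDir, "conservation_profiles.tsv"))
      report$profileCenterMeans <- vapply(prof, function(p)
        p$mean[p$offset == 0], 0)
    }
    if (!is.null(cfg$uce)) {
      uces <- tryCatch(readPeaksBed(cfg$uce),
                       error = function(e) GenomicRanges::GRanges())
      report$uceFractions <- vapply(nonEmpty, function(g)
        uceOverlapFraction(g, uces)$fraction, 0)
      writeTsv(data.frame(set = names(report$uceFractions),
                          fraction = report$uceFractions),
               file.path(cfg$outDir, "uce_fractions.tsv"))
    }
    if (!is.null(cfg$segmentation)) {
      seg <- readSegmentationBed(cfg$segmentation)
      stRows <- list()
      for (nm in names(nonEmpty)) {
        se <- stateEnrichment(nonEmpty[[nm]], seg, assembly, cfg$binWidth)
        se$set <- nm
        stRows[[nm]] <- se
      }
      stateTab <- do.call(rbind, c(stRows, list(make.row.names = FALSE)))
      writeTsv(stateTab, file.path(cfg$outDir, "state_enrichment.tsv"))
      report$stateArgmax <- vapply(stRows, function(se)
        as.character(se$state[which.max(se$fraction)]), "")
    }
  }

  ## stage: enhancers
  if (is.null(cfg$enhancers)) {
    report$skipped <- c(report$skipped, "enhancers: no catalog supplied")
    say("stage enhancers SKIPPED")
  } else {
    say("stage enhancers")
    catalog <- readEnhancerCatalog(cfg$enhancers)
    enhRows <- list()
    for (nm in names(nonEmpty)) {
      su <- summarizeEnhancerOverlap(nonEmpty[[nm]], catalog)
      tab <- su$perTissue
      tab$set <- nm
      tab$uniqueCRMs <- su$uniqueCRMs
      enhRows[[nm]] <- tab
    }
    enhTab <- do.call(rbind, c(enhRows, list(make.row.names = FALSE)))
    writeTsv(enhTab, file.path(cfg$outDir, "enhancer_overlap.tsv"))
    report$enhancerOverlap <- enhTab
  }

  jsonlite::write_json(reportForJson(report),
                       file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

# Chromatin state at peak centers ("UNASSIGNED" in gaps).
centerState <- function(peaks, segmentation) {
  ctr <- peakCenter(peaks)
  hit <- GenomicRanges::findOverlaps(ctr, segmentation,
                                     ignore.strand = TRUE)
  st <- rep("UNASSIGNED", length(ctr))
  st[S4Vectors::queryHits(hit)] <- as.character(
    GenomicRanges::mcols(segmentation)$state[S4Vectors::subjectHits(hit)])
  st
}

# Deterministic hash of the analysis configuration. The output
# directory is not part of the analysis, so two runs of the same inputs
# into different directories hash identically.
digestConfig <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outDir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small rolling hash; stable across sessions
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

reportForJson <- function(report) {
  rapply(report, function(x) x, how = "replace")
}
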