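#' Build a synthetic-bundle generator configuration
#'
#' Returns the full configuration driving [generateBundle()], with every
#' field overridable. Defaults define the "fig-mimic" scenario: a
#' wing-rich asymmetry for the two sequence-specific factors (about 2000
#' wing-specific events each versus about 150 eye-antenna-specific), a
#' coactivator-like factor with almost no tissue-specific binding, a 46%
#' promoter share for tissue-shared events, a Polycomb-state (BLUE) bias
#' for tissue-specific events, motif-plant rates of 0.51 in BLUE versus
#' 0.37 in YELLOW chromatin, and conservation elevated at
#' tissue-specific peaks.
#'
#' Peaks are laid out on disjoint fixed-width genomic slots so that the
#' classifier's ground truth is exact: tissue-shared sites carry
#' overlapping peaks at both tiers in both tissues, tissue-specific
#' sites carry peaks in one tissue only, and no foreign permissive peak
#' can stray into another site's slot.
#'
#' @param seed master seed; every emitted byte is a function of it.
#' @param ... overrides for any default field (see the function body for
#'   the full list; unknown names are an error).
#' @return A list of class `"discChIPGeneratorConfig"`.
#' @export
generatorConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    nChroms = 6L,
    chromLength = 7500000L,
    slotWidth = 2000L,
    tissues = c("W", "EA"),   # first entry anchors sharedFraction
    factors = list(
      Sd  = list(nPeaks = c(W = 3500L, EA = 1650L),
                 sharedFraction = 1500 / 3500, pattern = "GGAATG"),
      Hth = list(nPeaks = c(W = 3500L, EA = 1650L),
                 sharedFraction = 1500 / 3500,
                 pattern = "TGAY{N0-2}TGAY"),
      Yki = list(nPeaks = c(W = 2650L, EA = 2650L),
                 sharedFraction = 2500 / 2650, pattern = NULL)),
    fdr25Inflation = 0.25,    # extra permissive-only peaks per FDR1 peak
    nHubs = 1500L,            # slots where shared binding colocalizes
    hubFraction = 0.5,        # share of each factor's shared sites on hubs
    fdr1HalfWidth = 200L,
    fdr25Pad = 150L,
    tissueJitter = 50L,
    stateShares = c(YELLOW = 0.16, RED = 0.13, BLUE = 0.15,
                    GREEN = 0.10, BLACK = 0.46),
    stateBias = list(
      shared   = c(YELLOW = 0.55, RED = 0.27, BLUE = 0.12,
                   GREEN = 0.03, BLACK = 0.03),
      specific = c(YELLOW = 0.15, RED = 0.30, BLUE = 0.32,
                   GREEN = 0.10, BLACK = 0.13)),
    regionProfile = list(
      shared   = c(PROMOTER = 0.46, EXON = 0.06, INTRON = 0.18,
                   INTERGENIC = 0.30),
      specific = c(PROMOTER = 0.08, EXON = 0.05, INTRON = 0.37,
                   INTERGENIC = 0.50)),
    motifRateByState = c(YELLOW = 0.37, RED = 0.45, BLUE = 0.51,
                         GREEN = 0.30, BLACK = 0.30),
    uceRate = c(shared = 0.05, specific = 0.30),
    uceLength = 60L,
    consBackground = 0.10,
    consInside = c(shared = 0.35, specific = 0.75),
    consHalfWidth = 100L,
    consWindow = 600L,
    catalogSize = 600L,
    catalogComposition = c(specificW = 0.35, shared = 0.25,
                           background = 0.40),
    fragmentHalfWidth = 900L,
    fragmentDuplicateRate = 0.10,  # shifted copies -> mergeable CRMs
    activityRates = list(
      specificW  = c(eye = 0.55, antenna = 0.20, leg = 0.25, wing = 0.90),
      shared     = c(eye = 0.60, antenna = 0.30, leg = 0.30, wing = 0.60),
      background = c(eye = 0.25, antenna = 0.25, leg = 0.25, wing = 0.25)),
    nGenes = 7000L,
    nGeneSets = 12L,
    geneSetSize = 80L,
    scoreMean = c(shared = 15, specific = 8),
    scoreSd = 2)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validateGeneratorConfig(cfg)
  class(cfg) <- "discChIPGeneratorConfig"
  cfg
}

validateGeneratorConfig <- function(cfg) {
  stopifnot(abs(sum(cfg$stateShares) - 1) < 1e-9,
            all(names(cfg$stateShares) == CHROMATIN_STATES),
            length(cfg$tissues) == 2L)
  for (f in names(cfg$factors)) {
    fc <- cfg$factors[[f]]
    if (!all(cfg$tissues %in% names(fc$nPeaks)))
      stop("factor ", f, ": nPeaks must name both tissues")
    sf <- fc$sharedFraction
    if (sf < 0 || sf > 1) stop("sharedFraction outside [0,1] for ", f)
    nShared <- round(sf * fc$nPeaks[[cfg$tissues[1]]])
    if (fc$nPeaks[[cfg$tissues[2]]] < nShared)
      stop("factor ", f, ": second tissue has fewer peaks than shared events")
  }
  for (p in cfg$regionProfile)
    if (abs(sum(p) - 1) > 1e-9) stop("region profile must sum to 1")
  invisible(TRUE)
}

# Parse a compact pattern string ("GGAATG" or "TGAY{N0-2}TGAY").
parsePatternString <- function(s) {
  if (is.null(s)) return(NULL)
  m <- regmatches(s, regexec("^([A-Z]+)\\{N(\\d+)-(\\d+)\\}([A-Z]+)$", s))[[1]]
  if (length(m))
    IUPACPattern(m[2], m[5], as.integer(m[3]), as.integer(m[4]), name = s)
  else IUPACPattern(s, name = s)
}

# Draw one concrete instance of a pattern (uniform over degenerate
# choices, spacer lengths and strand).
sampleInstance <- function(pattern) {
  pick <- function(iupac) paste(vapply(strsplit(iupac, "")[[1]], function(sym)
    sample(setdiff(IUPAC_SETS[[sym]], "N"), 1), ""), collapse = "")
  s <- pick(pattern@halfSite1)
  if (isDimer(pattern)) {
    k <- sample(pattern@spacerMin:pattern@spacerMax, 1)
    s <- paste0(s, paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                         collapse = ""), pick(pattern@halfSite2))
  }
  if (stats::runif(1) < 0.5) s <- revcompString(s)
  s
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A window sequence free of every listed pattern, with instances planted
# for the flagged patterns. plantAt: offsets (1-based within window).
composeWindow <- function(width, patterns, plant, plantAt) {
  for (try in seq_len(200)) {
    s <- randomDna(width)
    ok <- all(vapply(patterns, function(p)
      nrow(scanPattern(s, p)) == 0L, logical(1)))
    if (!ok) next
    if (any(plant)) {
      for (i in which(plant)) {
        inst <- sampleInstance(patterns[[i]])
        at <- plantAt[i]
        substr(s, at, at + nchar(inst) - 1L) <- inst
      }
      # planting one instance must not fabricate or destroy another
      # pattern's evidence
      good <- all(vapply(seq_along(patterns), function(i)
        (nrow(scanPattern(s, patterns[[i]])) > 0L) == plant[i], logical(1)))
      if (!good) next
    }
    return(s)
  }
  stop("could not compose a motif-constrained window after 200 attempts")
}

#' Generate a complete synthetic input bundle
#'
#' Emits every file the pipeline consumes -- genome FASTA, chromosome
#' sizes, gene models (GFF3), four BED peak files per factor (two
#' tissues x two FDR tiers), chromatin-state segmentation BED,
#' conservation bedGraph, ultraconserved-element BED, enhancer-catalog
#' TSV, gene-set GMT and a consensus motif list -- plus a ground-truth
#' manifest (JSON) recording every planted property. The same
#' configuration yields byte-identical output.
#'
#' @param config a [generatorConfig()] list.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `manifest` (the in-memory truth manifest).
#' @export
generateBundle <- function(config, outDir) {
  stopifnot(inherits(config, "discChIPGeneratorConfig"))
  cfg <- config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tis <- cfg$tissues
  chromNames <- paste0("chr", seq_len(cfg$nChroms))
  chromSizes <- stats::setNames(rep(cfg$chromLength, cfg$nChroms), chromNames)

  ## ---- slot layout and segmentation (stream 1) ----
  set.seed(cfg$seed + 1L)
  perChrom <- floor(cfg$chromLength / cfg$slotWidth)
  nSlots <- perChrom * cfg$nChroms
  slotChrom <- rep(chromNames, each = perChrom)
  slotStart <- rep((seq_len(perChrom) - 1L) * cfg$slotWidth + 1L, cfg$nChroms)
  slotCenter <- slotStart + cfg$slotWidth %/% 2L - 1L
  slotState <- sample(CHROMATIN_STATES, nSlots, replace = TRUE,
                      prob = cfg$stateShares)

  ## ---- site allocation (stream 2) ----
  set.seed(cfg$seed + 2L)
  free <- sample(nSlots)   # permutation; consumed per state / any
  freeByState <- split(free, slotState[free])
  takeSlots <- function(states) {
    idx <- integer(length(states))
    for (s in unique(states)) {
      want <- which(states == s)
      pool <- freeByState[[s]]
      if (length(pool) < length(want))
        stop("infeasible config: not enough ", s, " slots (need ",
             length(want), ", have ", length(pool), ")")
      idx[want] <- pool[seq_along(want)]
      freeByState[[s]] <<- pool[-seq_along(want)]
    }
    idx
  }
  takeAny <- function(n) {
    pool <- unlist(freeByState, use.names = FALSE)
    if (length(pool) < n) stop("infeasible config: genome capacity exceeded")
    got <- pool[seq_len(n)]
    freeByState <<- split(setdiff(pool, got), slotState[setdiff(pool, got)])
    got
  }

  drawStates <- function(n, bias) sample(CHROMATIN_STATES, n, replace = TRUE,
                                         prob = bias)
  hubSlots <- takeSlots(drawStates(cfg$nHubs, cfg$stateBias$shared))

  sites <- list()   # one row per genomic site
  addSite <- function(slot, class, factorName, tissue) {
    sites[[length(sites) + 1L]] <<- data.frame(
      slot = slot, class = class, factorName = factorName,
      tissue = tissue, stringsAsFactors = FALSE)
  }
  for (f in names(cfg$factors)) {
    fc <- cfg$factors[[f]]
    nShared <- round(fc$sharedFraction * fc$nPeaks[[tis[1]]])
    nHubShared <- min(round(cfg$hubFraction * nShared), cfg$nHubs)
    if (nHubShared > 0)
      for (sl in sample(hubSlots, nHubShared)) addSite(sl, "shared", f, NA)
    nOwn <- nShared - nHubShared
    if (nOwn > 0)
      for (sl in takeSlots(drawStates(nOwn, cfg$stateBias$shared)))
        addSite(sl, "shared", f, NA)
    for (t in tis) {
      nSpec <- fc$nPeaks[[t]] - nShared
      if (nSpec > 0)
        for (sl in takeSlots(drawStates(nSpec, cfg$stateBias$specific)))
          addSite(sl, "specific", f, t)
      nExtra <- round(cfg$fdr25Inflation * fc$nPeaks[[t]])
      if (nExtra > 0)
        for (sl in takeAny(nExtra)) addSite(sl, "extra", f, t)
    }
  }
  sites <- do.call(rbind, sites)
  sites$state <- slotState[sites$slot]
  sites$chrom <- slotChrom[sites$slot]
  sites$center <- slotCenter[sites$slot]

  ## ---- peaks (stream 3) ----
  set.seed(cfg$seed + 3L)
  hw <- cfg$fdr1HalfWidth; pad <- cfg$fdr25Pad
  peakRows <- list()
  addPeak <- function(siteId, f, t, tier, start, end, class, state, score) {
    peakRows[[length(peakRows) + 1L]] <<- data.frame(
      siteId = siteId, factorName = f, tissue = t, tier = tier,
      chrom = sites$chrom[siteId], start = start, end = end,
      class = class, state = state, score = score, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sites))) {
    cl <- sites$class[i]; f <- sites$factorName[i]; c0 <- sites$center[i]
    tset <- if (cl == "shared") tis else sites$tissue[i]
    for (t in tset) {
      j <- sample(-cfg$tissueJitter:cfg$tissueJitter, 1)
      s1 <- c0 - hw + j; e1 <- c0 + hw - 1L + j
      score <- round(stats::rnorm(1,
        cfg$scoreMean[[if (cl == "shared") "shared" else "specific"]],
        cfg$scoreSd), 1)
      if (cl != "extra")
        addPeak(i, f, t, 1L, s1, e1, cl, sites$state[i], score)
      addPeak(i, f, t, 25L, s1 - pad, e1 + pad, cl, sites$state[i], score)
    }
  }
  peaks <- do.call(rbind, peakRows)
  peaks$id <- sprintf("pk%05d", seq_len(nrow(peaks)))

  ## one peak-bearing slot = one genomic site; hub slots host shared
  ## sites of several factors, so region/motif/conservation truth is
  ## drawn once per slot and applied to every factor present there
  occ <- sites$class %in% c("shared", "specific")
  slotTab <- unique(data.frame(slot = sites$slot[occ],
                               class = sites$class[occ],
                               stringsAsFactors = FALSE))
  if (anyDuplicated(slotTab$slot))
    stop("internal error: slot hosts two site classes")
  slotTab$state <- slotState[slotTab$slot]
  slotTab$chrom <- slotChrom[slotTab$slot]
  slotTab$center <- slotCenter[slotTab$slot]

  ## ---- genes and regions (stream 4) ----
  set.seed(cfg$seed + 4L)
  geneRows <- list(); slotRegion <- rep(NA_character_, nrow(slotTab))
  addGene <- function(chrom, body, exons, strand, role) {
    geneRows[[length(geneRows) + 1L]] <<- list(
      chrom = chrom, body = body, exons = exons, strand = strand,
      role = role)
  }
  for (i in seq_len(nrow(slotTab))) {
    cl <- slotTab$class[i]
    prof <- cfg$regionProfile[[if (cl == "shared") "shared" else "specific"]]
    region <- sample(names(prof), 1, prob = prof)
    slotRegion[i] <- region
    if (region == "INTERGENIC") next
    c0 <- slotTab$center[i]
    strand <- sample(c("+", "-"), 1)
    ch <- slotTab$chrom[i]
    role <- paste0(cl, "_", tolower(region))
    if (region == "PROMOTER") {
      d <- sample(50:950, 1)
      if (strand == "+")
        addGene(ch, c(c0 + d, c0 + d + 799L), list(c(c0 + d, c0 + d + 799L)),
                "+", role)
      else
        addGene(ch, c(c0 - d - 799L, c0 - d), list(c(c0 - d - 799L, c0 - d)),
                "-", role)
    } else if (region == "EXON") {
      if (strand == "+")
        addGene(ch, c(c0 - 100L, c0 + 699L),
                list(c(c0 - 100L, c0 + 299L), c(c0 + 500L, c0 + 699L)),
                "+", role)
      else
        addGene(ch, c(c0 - 699L, c0 + 100L),
                list(c(c0 - 699L, c0 - 500L), c(c0 - 299L, c0 + 100L)),
                "-", role)
    } else {  # INTRON
      addGene(ch, c(c0 - 900L, c0 + 899L),
              list(c(c0 - 900L, c0 - 701L), c(c0 + 700L, c0 + 899L)),
              strand, role)
    }
  }
  sites$region <- slotRegion[match(sites$slot, slotTab$slot)]
  nBackground <- max(0L, cfg$nGenes - length(geneRows))
  if (nBackground > 0)
    for (sl in takeAny(nBackground)) {
      c0 <- slotCenter[sl]
      addGene(slotChrom[sl], c(c0 - 400L, c0 + 399L),
              list(c(c0 - 400L, c0 + 399L)), sample(c("+", "-"), 1),
              "background")
    }
  geneIds <- sprintf("g%05d", seq_along(geneRows))

  ## ---- motifs (stream 5) ----
  set.seed(cfg$seed + 5L)
  patterns <- lapply(cfg$factors, function(fc) parsePatternString(fc$pattern))
  patterns <- patterns[!vapply(patterns, is.null, logical(1))]
  # The composed window must strictly contain every FDR1 extent at the
  # site with enough margin that no chance match can straddle the
  # window/background junction and still touch a peak.
  winHalf <- hw + cfg$tissueJitter
  margin <- 16L
  peaks$motifPlanted <- FALSE
  peakSlot <- sites$slot[peaks$siteId]
  siteWindows <- list()
  for (i in seq_len(nrow(slotTab))) {
    sl <- slotTab$slot[i]
    present <- intersect(
      unique(peaks$factorName[peakSlot == sl & peaks$tier == 1L]),
      names(patterns))
    if (!length(present)) next
    pats <- patterns[present]
    plant <- stats::runif(length(pats)) <
      cfg$motifRateByState[[slotTab$state[i]]]
    width <- 2L * (winHalf + margin)
    # plant offsets near the window center, spread out if several factors
    mid <- winHalf + margin
    plantAt <- mid + seq(-40L, 40L, length.out = max(length(pats), 2L) +
                         2L)[seq_along(pats) + 1L]
    s <- composeWindow(width, pats, plant, round(plantAt))
    siteWindows[[length(siteWindows) + 1L]] <- list(
      chrom = slotTab$chrom[i],
      start = slotTab$center[i] - winHalf - margin + 1L,
      seq = s)
    for (k in seq_along(present))
      peaks$motifPlanted[peakSlot == sl &
                         peaks$factorName == present[k]] <- plant[k]
  }

  ## ---- conservation and UCEs (stream 6) ----
  set.seed(cfg$seed + 6L)
  consRows <- list(); uceRows <- list()
  peaks$uce <- FALSE
  for (i in seq_len(nrow(slotTab))) {
    cl <- slotTab$class[i]; c0 <- slotTab$center[i]; ch <- slotTab$chrom[i]
    lvl <- cfg$consInside[[cl]]
    wh <- cfg$consHalfWidth; ww <- cfg$consWindow
    consRows[[length(consRows) + 1L]] <- data.frame(
      chrom = ch,
      start = c(c0 - ww, c0 - wh, c0 + wh + 1L),
      end = c(c0 - wh - 1L, c0 + wh, c0 + ww),
      score = c(cfg$consBackground, lvl, cfg$consBackground))
    if (stats::runif(1) < cfg$uceRate[[cl]]) {
      half <- cfg$uceLength %/% 2L
      uceRows[[length(uceRows) + 1L]] <- data.frame(
        chrom = ch, start = c0 - half, end = c0 + half - 1L)
      peaks$uce[peakSlot == slotTab$slot[i]] <- TRUE
    }
  }

  ## ---- enhancer catalog (stream 7) ----
  set.seed(cfg$seed + 7L)
  poolSpecW <- which(sites$class == "specific" & sites$tissue == tis[1])
  poolShared <- which(sites$class == "shared")
  src <- sample(names(cfg$catalogComposition), cfg$catalogSize,
                replace = TRUE, prob = cfg$catalogComposition)
  if (!length(poolSpecW)) src[src == "specificW"] <- "background"
  if (!length(poolShared)) src[src == "shared"] <- "background"
  fragRows <- list()
  fh <- cfg$fragmentHalfWidth
  for (k in seq_len(cfg$catalogSize)) {
    if (src[k] == "background") {
      sl <- takeAny(1L); ch <- slotChrom[sl]; c0 <- slotCenter[sl]
    } else {
      i <- if (src[k] == "specificW") sample(poolSpecW, 1)
           else sample(poolShared, 1)
      ch <- sites$chrom[i]; c0 <- sites$center[i]
    }
    fragRows[[length(fragRows) + 1L]] <- data.frame(
      src = src[k], chrom = ch, start = c0 - fh, end = c0 + fh - 1L,
      stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, fragRows)
  dup <- which(stats::runif(nrow(frags)) < cfg$fragmentDuplicateRate)
  if (length(dup)) {
    copies <- frags[dup, , drop = FALSE]
    copies$start <- copies$start + 300L; copies$end <- copies$end + 300L
    frags <- rbind(frags, copies)
  }
  frags$id <- sprintf("E%04d", seq_len(nrow(frags)))
  for (tisname in CATALOG_TISSUES)
    frags[[tisname]] <- stats::runif(nrow(frags)) <
      vapply(frags$src, function(s) cfg$activityRates[[s]][[tisname]], 0)

  ## ---- genome sequence (stream 8) ----
  set.seed(cfg$seed + 8L)
  seqs <- lapply(chromNames, function(ch) {
    s <- Biostrings::DNAString(randomDna(cfg$chromLength))
    wins <- Filter(function(w) w$chrom == ch, siteWindows)
    if (length(wins)) {
      at <- IRanges::IRanges(vapply(wins, `[[`, 0, "start"),
                             width = vapply(wins, function(w) nchar(w$seq), 0))
      o <- order(IRanges::start(at))
      s <- Biostrings::replaceAt(s, at[o],
             as(vapply(wins, `[[`, "", "seq")[o], "DNAStringSet"))
    }
    s
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chromNames
  assembly <- GenomeAssembly(chromSizes, genome)

  ## ---- gene sets (stream 9) ----
  set.seed(cfg$seed + 9L)
  roles <- vapply(geneRows, `[[`, "", "role")
  hkPool <- geneIds[startsWith(roles, "shared_")]
  devPool <- geneIds[startsWith(roles, "specific_")]
  sets <- list()
  pickSet <- function(pool, n) {
    n1 <- min(round(0.7 * n), length(pool))
    c(sample(pool, n1), sample(setdiff(geneIds, pool),
                               max(n - n1, 0)))
  }
  sets[["housekeeping_like"]] <- pickSet(hkPool, cfg$geneSetSize)
  sets[["patterning_like"]] <- pickSet(devPool, cfg$geneSetSize)
  for (k in seq_len(max(cfg$nGeneSets - 2L, 0L)))
    sets[[sprintf("random_set_%02d", k)]] <-
      sample(geneIds, cfg$geneSetSize)

  ## ---- write the bundle ----
  paths <- list(
    genome = file.path(outDir, "genome.fa"),
    chromSizes = file.path(outDir, "chrom.sizes"),
    genes = file.path(outDir, "genes.gff3"),
    segmentation = file.path(outDir, "segmentation.bed"),
    conservation = file.path(outDir, "conservation.bedGraph"),
    uce = file.path(outDir, "uce.bed"),
    enhancers = file.path(outDir, "enhancers.tsv"),
    geneSets = file.path(outDir, "genesets.gmt"),
    motifs = file.path(outDir, "motifs.txt"),
    manifest = file.path(outDir, "manifest.json"))
  Biostrings::writeXStringSet(genome, paths$genome)
  writeChromSizes(assembly, paths$chromSizes)

  gBodies <- GenomicRanges::GRanges(
    vapply(geneRows, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(geneRows, function(g) g$body[1], 0),
                     vapply(geneRows, function(g) g$body[2], 0)),
    strand = vapply(geneRows, `[[`, "", "strand"))
  exl <- GenomicRanges::GRangesList(lapply(seq_along(geneRows), function(i) {
    ex <- geneRows[[i]]$exons
    GenomicRanges::GRanges(geneRows[[i]]$chrom,
      IRanges::IRanges(vapply(ex, `[`, 0, 1), vapply(ex, `[`, 0, 2)),
      strand = geneRows[[i]]$strand)
  }))
  models <- makeGeneModels(gBodies, geneIds, exl)
  writeGeneModelsGff3(models, paths$genes)

  segRanges <- GenomicRanges::GRanges(slotChrom,
    IRanges::IRanges(slotStart, width = cfg$slotWidth))
  # pad chromosome tails (beyond the last full slot) as BLACK
  tailLen <- cfg$chromLength - perChrom * cfg$slotWidth
  segState <- slotState
  if (tailLen > 0) {
    tails <- GenomicRanges::GRanges(chromNames,
      IRanges::IRanges(perChrom * cfg$slotWidth + 1L, cfg$chromLength))
    segRanges <- c(segRanges, tails)
    segState <- c(segState, rep("BLACK", cfg$nChroms))
  }
  o <- order(as.character(GenomicRanges::seqnames(segRanges)),
             GenomicRanges::start(segRanges))
  segRanges <- segRanges[o]; segState <- segState[o]
  GenomicRanges::mcols(segRanges)$name <- segState
  rtracklayer::export(segRanges, paths$segmentation, format = "BED")

  cons <- do.call(rbind, consRows)
  consGr <- GenomicRanges::GRanges(cons$chrom,
    IRanges::IRanges(cons$start, cons$end), score = cons$score)
  writeSignalTrack(signalToRleList(consGr, assembly), paths$conservation)

  if (length(uceRows)) {
    uce <- do.call(rbind, uceRows)
    writePeaksBed(GenomicRanges::GRanges(uce$chrom,
      IRanges::IRanges(uce$start, uce$end)), paths$uce)
  } else writeLines(character(0), paths$uce)

  catalog <- GenomicRanges::GRanges(frags$chrom,
    IRanges::IRanges(frags$start, frags$end))
  GenomicRanges::mcols(catalog)$id <- frags$id
  for (tisname in CATALOG_TISSUES)
    GenomicRanges::mcols(catalog)[[tisname]] <- frags[[tisname]]
  writeEnhancerCatalog(catalog, paths$enhancers)

  writeGeneSets(sets, paths$geneSets)
  writeConsensusMotifs(patterns, paths$motifs)

  for (f in names(cfg$factors)) for (t in tis) for (tier in c(1L, 25L)) {
    sel <- peaks$factorName == f & peaks$tissue == t & peaks$tier == tier
    gr <- GenomicRanges::GRanges(peaks$chrom[sel],
      IRanges::IRanges(peaks$start[sel], peaks$end[sel]),
      name = peaks$id[sel], score = peaks$score[sel])
    p <- file.path(outDir, sprintf("%s_%s_fdr%d.bed", f, t, tier))
    paths[[sprintf("peaks_%s_%s_fdr%d", f, t, tier)]] <- p
    writePeaksBed(gr, p)
  }

  manifest <- list(
    seed = cfg$seed,
    tissues = tis,
    factors = stats::setNames(lapply(names(cfg$factors), function(f) {
      fc <- cfg$factors[[f]]
      nShared <- round(fc$sharedFraction * fc$nPeaks[[tis[1]]])
      list(pattern = if (is.null(fc$pattern)) NA else fc$pattern,
           nShared = nShared,
           nSpecific = stats::setNames(
             as.list(vapply(tis, function(t)
               as.numeric(fc$nPeaks[[t]] - nShared), 0)), tis))
    }), names(cfg$factors)),
    peaks = peaks[, c("id", "factorName", "tissue", "tier", "chrom",
                      "start", "end", "class", "state", "motifPlanted",
                      "uce")],
    genes = data.frame(gene_id = geneIds, role = roles,
                       stringsAsFactors = FALSE),
    fragments = frags[, c("id", "src", CATALOG_TISSUES)],
    regionProfile = cfg$regionProfile,
    siteRegions = as.data.frame(table(class = sites$class,
                                      region = sites$region)))
  manifest$peaks$start <- manifest$peaks$start - 1L  # manifest in BED coords
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(list(paths = paths, manifest = manifest, config = cfg))
}

#' Re-verify a bundle against its truth manifest
#'
#' Reloads the emitted files and checks every machine-checkable claim:
#' tier nesting for each factor/tissue, classification ground truth
#' (shared peaks overlap the partner tissue's permissive set, specific
#' peaks do not), planted-motif claims by re-scanning each stringent
#' peak, chromatin-state claims against the segmentation, and
#' ultraconserved-element claims against the UCE intervals.
#'
#' @param dir bundle directory written by [generateBundle()].
#' @param maxReported cap on reported failures (default 20).
#' @return List with `pass` (logical) and `failures` (character vector
#'   naming the offending records).
#' @export
validateManifest <- function(dir, maxReported = 20) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  pk <- as.data.frame(man$peaks, stringsAsFactors = FALSE)
  pk$start <- pk$start + 1L   # back to 1-based
  fails <- character(0)
  note <- function(msg) if (length(fails) < maxReported)
    fails <<- c(fails, msg)
  asm <- readGenomeFasta(file.path(dir, "genome.fa"))
  seg <- readSegmentationBed(file.path(dir, "segmentation.bed"))
  uce <- tryCatch(readPeaksBed(file.path(dir, "uce.bed")),
                  error = function(e) GenomicRanges::GRanges())
  motifs <- readConsensusMotifs(file.path(dir, "motifs.txt"))
  tis <- man$tissues
  for (f in names(man$factors)) {
    grs <- list()
    for (t in tis) for (tier in c(1L, 25L)) {
      p <- file.path(dir, sprintf("%s_%s_fdr%d.bed", f, t, tier))
      grs[[sprintf("%s_%d", t, tier)]] <- readPeaksBed(p)
    }
    for (t in tis) {
      ok <- tryCatch({
        DualTierPeaks(f, t, grs[[sprintf("%s_1", t)]],
                      grs[[sprintf("%s_25", t)]]); TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) note(sprintf("%s/%s: %s", f, t, ok))
    }
    sub <- pk[pk$factorName == f & pk$tier == 1L, , drop = FALSE]
    gr1 <- GenomicRanges::GRanges(sub$chrom,
      IRanges::IRanges(sub$start, sub$end))
    # classification truth
    for (t in tis) {
      partner <- setdiff(tis, t)
      selT <- sub$tissue == t
      shared <- IRanges::overlapsAny(gr1[selT],
        grs[[sprintf("%s_25", partner)]])
      want <- sub$class[selT] == "shared"
      bad <- which(shared != want)
      for (b in utils::head(bad, 5))
        note(sprintf("class mismatch for %s", sub$id[selT][b]))
    }
    # state claims at peak centers
    ctr <- peakCenter(gr1)
    hit <- GenomicRanges::findOverlaps(ctr, seg)
    st <- rep(NA_character_, length(ctr))
    st[S4Vectors::queryHits(hit)] <-
      as.character(GenomicRanges::mcols(seg)$state[S4Vectors::subjectHits(hit)])
    bad <- which(st != sub$state)
    for (b in utils::head(bad, 5))
      note(sprintf("state mismatch for %s (claimed %s, found %s)",
                   sub$id[b], sub$state[b], st[b]))
    # UCE claims
    ov <- IRanges::overlapsAny(gr1, uce)
    bad <- which(ov != sub$uce)
    for (b in utils::head(bad, 5))
      note(sprintf("UCE mismatch for %s", sub$id[b]))
    # motif claims
    patt <- man$factors[[f]]$pattern
    if (!is.null(patt) && !is.na(patt)) {
      pattern <- motifs[[patt]]
      if (is.null(pattern)) pattern <- parsePatternString(patt)
      seqs <- peakSequences(gr1, asm)
      has <- vapply(seqs, function(s)
        nrow(scanPattern(s, pattern)) > 0L, logical(1))
      bad <- which(has != sub$motifPlanted)
      for (b in utils::head(bad, 5))
        note(sprintf("motif mismatch for %s", sub$id[b]))
    }
  }
  list(pass = length(fails) == 0L, failures = fails)
}
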