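# IUPAC symbol -> set of matching sequence bases. Sequences are over
# A/C/G/T/N; a sequence N is matched only by the pattern symbol N.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      W = "W", S = "S", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

# All concrete pattern strings for one spacer length, as IUPAC strings
# with the spacer rendered as N's.
patternVariants <- function(pattern) {
  if (!isDimer(pattern)) return(pattern@halfSite1)
  vapply(pattern@spacerMin:pattern@spacerMax, function(k)
    paste0(pattern@halfSite1, strrep("N", k), pattern@halfSite2), "")
}

reverseComplementIupac <- function(s) {
  paste(rev(IUPAC_COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
}

# Match positions of a single IUPAC string in a character vector of
# bases; vectorized over start positions.
matchIupacString <- function(baseVec, iupac) {
  sym <- strsplit(iupac, "")[[1]]
  if (any(!sym %in% names(IUPAC_SETS)))
    stop("invalid IUPAC symbol '", sym[!sym %in% names(IUPAC_SETS)][1],
         "' in pattern")
  m <- length(sym); L <- length(baseVec)
  if (L < m) return(integer(0))
  starts <- seq_len(L - m + 1L)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(m)) {
    ok <- ok & (baseVec[starts + j - 1L] %in% IUPAC_SETS[[sym[j]]])
    if (!any(ok)) return(integer(0))
  }
  starts[ok]
}

#' Scan a sequence for a degenerate consensus or spaced dimer
#'
#' Reports every start position where each pattern symbol's IUPAC class
#' contains the sequence base, for every admissible spacer length.
#' Minus-strand matches are found by scanning the reverse complement and
#' mapping coordinates back to the forward strand; a minus-strand match
#' is reported at the forward-strand start of the matched stretch.
#' Sequences are over A/C/G/T/N, and N in the sequence is matched by no
#' pattern symbol except N.
#'
#' @param sequence a single character string or `DNAString`.
#' @param pattern an [IUPACPattern-class].
#' @param bothStrands scan the reverse complement too (default TRUE).
#' @return data.frame with one row per match: `start` (1-based, forward
#'   coordinates), `width`, `strand`. Every admissible spacer length is
#'   reported, so one start may yield several rows of different widths.
#' @examples
#' scanPattern("AAGGAATGAA", IUPACPattern("GGAATG"))
#' scanPattern("TGACTGAT", IUPACPattern("TGAY", "TGAY", 0, 2),
#'             bothStrands = FALSE)
#' @export
scanPattern <- function(sequence, pattern, bothStrands = TRUE) {
  s <- toupper(as.character(sequence))
  bases <- strsplit(s, "")[[1]]
  if (length(bases) && any(!bases %in% c("A", "C", "G", "T", "N")))
    stop("sequence must be over A/C/G/T/N")
  L <- length(bases)
  variants <- patternVariants(pattern)
  hits <- list()
  for (v in variants) {
    st <- matchIupacString(bases, v)
    if (length(st))
      hits[[length(hits) + 1L]] <-
        data.frame(start = st, width = nchar(v), strand = "+")
    if (bothStrands) {
      rcv <- reverseComplementIupac(v)
      if (rcv != v) {
        st <- matchIupacString(bases, rcv)
      } # palindromic variant: same starts, report on minus too
      if (length(st))
        hits[[length(hits) + 1L]] <-
          data.frame(start = st, width = nchar(v), strand = "-")
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), width = integer(0),
                      strand = character(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand, out$width), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of peaks containing at least one motif match
#'
#' "Containing the motif" means >= 1 match anywhere within the called
#' peak interval, on either strand.
#'
#' @param peaks `GRanges`.
#' @param assembly [GenomeAssembly-class] with sequence attached.
#' @param pattern an [IUPACPattern-class].
#' @return List: `fraction`, `hits` (numerator), `n` (denominator), and
#'   `hasMotif` (logical vector parallel to `peaks`).
#' @export
peakMotifFraction <- function(peaks, assembly, pattern) {
  if (!hasSequence(assembly)) stop("assembly carries no sequence")
  validateAgainstAssembly(peaks, assembly, "peak")
  seqs <- peakSequences(peaks, assembly)
  has <- vapply(seqs, function(s)
    nrow(scanPattern(s, pattern)) > 0L, logical(1))
  list(fraction = if (length(has)) mean(has) else NaN,
       hits = sum(has), n = length(has), hasMotif = unname(has))
}

# Extract peak sequences as plain character strings.
peakSequences <- function(peaks, assembly) {
  sq <- genomeSequence(assembly)
  sn <- as.character(GenomicRanges::seqnames(peaks))
  vapply(seq_along(peaks), function(i)
    as.character(Biostrings::subseq(sq[[sn[i]]],
                                    GenomicRanges::start(peaks)[i],
                                    GenomicRanges::end(peaks)[i])), "")
}

#' Two-sided Fisher exact comparison of two motif-containment fractions
#'
#' Tests the 2x2 table (with motif / without) x (group A / group B) with
#' Fisher's exact test, two-sided by the minimum-likelihood rule.
#'
#' @param hitsA,nA hits and total in group A.
#' @param hitsB,nB hits and total in group B.
#' @return The two-sided p-value.
#' @export
compareFractions <- function(hitsA, nA, hitsB, nB) {
  if (nA == 0 || nB == 0) stop("group sizes must be positive")
  if (hitsA > nA || hitsB > nB) stop("hits exceed group size")
  tab <- matrix(c(hitsA, nA - hitsA, hitsB, nB - hitsB), nrow = 2)
  stats::fisher.test(tab)$p.value
}

#' Hamming distance between equal-length sequences
#'
#' @param wild,mutant character strings of equal length.
#' @return Integer count of substituted positions.
#' @examples
#' countSubstitutions("GACAG", "GGGGG")  # 3
#' @export
countSubstitutions <- function(wild, mutant) {
  w <- strsplit(toupper(as.character(wild)), "")[[1]]
  m <- strsplit(toupper(as.character(mutant)), "")[[1]]
  if (length(w) != length(m)) stop("sequences differ in length")
  sum(w != m)
}

#' Replace motif matches with mutant sequence
#'
#' Site-directed mutagenesis in silico: each listed match is replaced by
#' a same-length replacement string, as when testing enhancer function
#' by knocking out all occurrences of a binding site.
#'
#' @param sequence character string or `DNAString`.
#' @param matches data.frame from [scanPattern()] (forward-strand
#'   coordinates; minus-strand matches are replaced over the same
#'   stretch).
#' @param replacement a single replacement string recycled to every site
#'   (must match each site's width), or a character vector with one
#'   entry per match.
#' @return List: `sequence` (mutated), `substitutions` (total Hamming
#'   distance over all sites).
#' @export
mutateSites <- function(sequence, matches, replacement) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  if (!nrow(matches))
    return(list(sequence = paste(s, collapse = ""), substitutions = 0L))
  rep <- if (length(replacement) == 1L)
    rep(replacement, nrow(matches)) else replacement
  if (length(rep) != nrow(matches))
    stop("need one replacement per match")
  o <- order(matches$start)
  matches <- matches[o, , drop = FALSE]; rep <- rep[o]
  ends <- matches$start + matches$width - 1L
  if (any(matches$start[-1] <= ends[-length(ends)]))
    stop("overlapping replacement sites")
  total <- 0L
  for (i in seq_len(nrow(matches))) {
    if (nchar(rep[i]) != matches$width[i])
      stop("replacement length differs from site length at site ", i)
    idx <- matches$start[i]:ends[i]
    r <- strsplit(toupper(rep[i]), "")[[1]]
    total <- total + sum(s[idx] != r)
    s[idx] <- r
  }
  list(sequence = paste(s, collapse = ""), substitutions = total)
}

#' Central enrichment of motifs within fixed-width peak sequences
#'
#' For each motif, the single best site per sequence is kept (consensus
#' patterns: all matches tie on score, so the site closest to the
#' sequence center wins, then the leftmost; PWMs: highest log-odds
#' score, same tie-breaks). Each candidate center-symmetric window of
#' match-start positions is then tested with an upper-tail binomial:
#' success probability = window positions / total admissible start
#' positions, trials = sequences contributing a site. The best window's
#' p-value is reported and the E-value is `p * librarySize`. Motifs with
#' E-value at or below the threshold are flagged significant.
#'
#' @param sequences character vector of equal-length peak sequences
#'   (peaks resized around their centers).
#' @param library named list of motifs: [IUPACPattern-class] objects
#'   and/or numeric PWM probability matrices (rows A,C,G,T).
#' @param windowWidths candidate central-window widths, in start
#'   positions; defaults to an odd-width ladder up to the admissible
#'   range. Give a single width for a calibrated (single-test) p-value.
#' @param librarySize E-value multiplier; defaults to `length(library)`.
#' @param eThreshold significance threshold on the E-value (default 10).
#' @return data.frame sorted by E-value: `motif`, `bestWindow`,
#'   `countInWindow`, `nSequences` (with a site), `pValue`, `eValue`,
#'   `significant`.
#' @export
centralEnrichment <- function(sequences, library, windowWidths = NULL,
                              librarySize = length(library),
                              eThreshold = 10) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must all have equal length")
  if (is.null(names(library)))
    names(library) <- paste0("motif", seq_along(library))
  rows <- lapply(names(library), function(nm) {
    motif <- library[[nm]]
    w <- if (methods::is(motif, "IUPACPattern")) patternMinWidth(motif)
         else ncol(motif)
    P <- L - w + 1L  # admissible start positions
    if (P < 1L) stop("motif '", nm, "' longer than the sequences")
    best <- vapply(sequences, function(s) bestSiteStart(s, motif), 0)
    best <- best[!is.na(best)]
    n <- length(best)
    widths <- windowWidths
    if (is.null(widths)) widths <- unique(pmin(P, c(1L, seq(3L, P, by = 2L))))
    center <- (1 + P) / 2
    res <- vapply(widths, function(wd) {
      half <- (wd - 1) / 2
      cnt <- sum(abs(best - center) <= half + 1e-9)
      p <- if (n > 0)
        stats::pbinom(cnt - 1, n, wd / P, lower.tail = FALSE) else 1
      c(wd, cnt, max(p, .Machine$double.xmin))
    }, numeric(3))
    i <- which.min(res[3, ])
    data.frame(motif = nm, bestWindow = res[1, i],
               countInWindow = res[2, i], nSequences = n,
               pValue = res[3, i],
               eValue = min(res[3, i] * librarySize, librarySize))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$eValue <= eThreshold
  out[order(out$eValue), , drop = FALSE]
}

# Best site start for one sequence: highest score, ties broken toward
# the sequence center then leftmost. NA when no site.
bestSiteStart <- function(s, motif) {
  if (methods::is(motif, "IUPACPattern")) {
    m <- scanPattern(s, motif)
    if (!nrow(m)) return(NA_real_)
    center <- (1 + nchar(s) - patternMinWidth(motif) + 1) / 2
    d <- abs(m$start - center)
    m$start[order(d, m$start)][1]
  } else {
    scorePlus <- pwmScoreAll(s, motif)
    scoreMinus <- rev(pwmScoreAll(revcompString(s), motif))
    sc <- pmax(scorePlus, scoreMinus)
    if (all(!is.finite(sc))) return(NA_real_)
    center <- (1 + length(sc)) / 2
    o <- order(-sc, abs(seq_along(sc) - center), seq_along(sc))
    o[1]
  }
}

revcompString <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Log-odds PWM score (0.25 uniform background) at every start position.
pwmScoreAll <- function(s, pwm) {
  bases <- strsplit(toupper(s), "")[[1]]
  w <- ncol(pwm); L <- length(bases)
  if (L < w) return(numeric(0))
  lo <- log2(pmax(pwm, 1e-4) / 0.25)
  rownames(lo) <- c("A", "C", "G", "T")
  idx <- match(bases, c("A", "C", "G", "T"))
  starts <- seq_len(L - w + 1L)
  sc <- numeric(length(starts))
  for (j in seq_len(w)) {
    b <- idx[starts + j - 1L]
    col <- lo[, j]
    sc <- sc + ifelse(is.na(b), -Inf, col[b])
  }
  sc
}

#' Read motifs from minimal MEME text format
#'
#' Parses `MOTIF` blocks with their letter-probability matrices into PWM
#' probability matrices (rows A, C, G, T) usable by
#' [centralEnrichment()]. Only the fields the package consumes are read.
#'
#' @param path MEME-format text file.
#' @return Named list of 4-row probability matrices.
#' @export
readMemeMotifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s+", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    nm <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    j <- starts[i] + 1L
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) stop("motif ", nm, " lacks a probability matrix")
    k <- j + 1L
    rows <- list()
    while (k <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[k])) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1]])
      k <- k + 1L
    }
    if (!length(rows)) stop("empty probability matrix for motif ", nm)
    out[[nm]] <- t(do.call(rbind, rows))
  }
  out
}

#' Write a plain-text consensus motif list
#'
#' One motif per line: name, half-site 1, half-site 2 (or `.`),
#' spacer range. Readable with [readConsensusMotifs()].
#'
#' @param patterns list of [IUPACPattern-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConsensusMotifs <- function(patterns, path) {
  writeLines(vapply(patterns, function(p)
    paste(p@name, p@halfSite1,
          if (isDimer(p)) p@halfSite2 else ".",
          p@spacerMin, p@spacerMax, sep = "\t"), ""), path)
  invisible(path)
}

#' Read a plain-text consensus motif list
#' @param path file written by [writeConsensusMotifs()].
#' @return Named list of [IUPACPattern-class].
#' @export
readConsensusMotifs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("name", "half1", "half2",
                                         "spacerMin", "spacerMax"))
  out <- lapply(seq_len(nrow(tab)), function(i)
    IUPACPattern(tab$half1[i],
                 if (tab$half2[i] == ".") "" else tab$half2[i],
                 tab$spacerMin[i], tab$spacerMax[i], name = tab$name[i]))
  stats::setNames(out, tab$name)
}
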