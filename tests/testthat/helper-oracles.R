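# Independent oracles used across the suite. Each reimplements the
# quantity under test by a different mechanism than the package code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Positionwise-union oracle for interval merging: mark covered bases on a
# small genome, then read back maximal runs.
oracleMergeMask <- function(gr, chromLen) {
  out <- list()
  for (ch in unique(as.character(seqnames(gr)))) {
    mask <- logical(chromLen)
    g <- gr[as.character(seqnames(gr)) == ch]
    for (i in seq_along(g)) mask[start(g)[i]:end(g)[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep))
      out[[ch]] <- GRanges(ch, IRanges(starts[keep], ends[keep]))
  }
  if (!length(out)) return(GRanges())
  suppressWarnings(sort(do.call(c, unname(out))))
}

# Direct log-space summation of the hypergeometric upper tail,
# independent of phyper.
oracleHyperTail <- function(N, K, n, k) {
  lo <- max(0L, n + K - N); hi <- min(n, K)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Two-sided Fisher exact p by full enumeration at fixed margins, summing
# probabilities of all tables at most as likely as the observed one.
oracleFisherTwoSided <- function(a, b, c, d) {
  n <- a + b + c + d; r1 <- a + b; c1 <- a + c
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  prob <- function(x) exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) -
                          lchoose(n, c1))
  pObs <- prob(a)
  xs <- lo:hi
  sum(vapply(xs, prob, 0)[vapply(xs, prob, 0) <= pObs * (1 + 1e-7)])
}

# Regex-lookahead oracle for IUPAC scanning (finds all overlapping
# matches per spacer length and strand through the PCRE engine).
iupacToRegex <- function(s) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           W = "[AT]", S = "[CG]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGTN]")
  paste(map[strsplit(s, "")[[1]]], collapse = "")
}

oracleScan <- function(seq, half1, half2 = "", smin = 0, smax = 0) {
  variants <- if (nzchar(half2))
    vapply(smin:smax, function(k)
      paste0(half1, strrep("N", k), half2), "") else half1
  out <- list()
  for (v in variants) for (str in c("+", "-")) {
    vv <- if (str == "+") v else discChIP:::reverseComplementIupac(v)
    m <- gregexpr(paste0("(?=", iupacToRegex(vv), ")"), seq,
                  perl = TRUE)[[1]]
    if (m[1] != -1)
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(m), width = nchar(v), strand = str)
  }
  if (!length(out))
    return(data.frame(start = integer(0), width = integer(0),
                      strand = character(0)))
  o <- do.call(rbind, out)
  o <- o[order(o$start, o$strand, o$width), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# Textbook Benjamini-Hochberg step-up.
oracleBH <- function(p) {
  m <- length(p); o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m); out[o] <- pmin(adj, 1)
  out
}

randomSeqs <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), "")
}
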