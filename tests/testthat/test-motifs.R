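test_that("literal and dimer patterns match where expected", {
  m <- scanPattern("AAGGAATGAA", IUPACPattern("GGAATG"))
  expect_equal(m$start, 3)  # 0-based position 2
  expect_equal(m$strand, "+")

  # TGAC + spacer 0 + TGAT satisfies TGAY{N0-2}TGAY
  d <- scanPattern("TGACTGAT", IUPACPattern("TGAY", "TGAY", 0, 2),
                   bothStrands = FALSE)
  expect_equal(d$start, 1)
  expect_equal(d$width, 8)

  # sequence N is matched by no symbol except pattern N
  expect_equal(nrow(scanPattern("AANAATGAA", IUPACPattern("GGAATG"))), 0)
  expect_equal(nrow(scanPattern("ANA", IUPACPattern("ANA"),
                                bothStrands = FALSE)), 1)

  expect_error(IUPACPattern("GGXATG"), "IUPAC")
})

test_that("scanning equals the regex oracle over random sequences", {
  set.seed(21)
  pats <- list(
    list(p = IUPACPattern("GGAATG"), h1 = "GGAATG", h2 = "", s = c(0, 0)),
    list(p = IUPACPattern("RGAATG"), h1 = "RGAATG", h2 = "", s = c(0, 0)),
    list(p = IUPACPattern("WGAY", "WGAY", 0, 2), h1 = "WGAY", h2 = "WGAY",
         s = c(0, 2)))
  for (i in 1:300) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    pp <- pats[[(i %% 3) + 1]]
    got <- scanPattern(s, pp$p)
    want <- oracleScan(s, pp$h1, pp$h2, pp$s[1], pp$s[2])
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$width, want$width)
  }
})

test_that("match sets mirror under reverse complement", {
  set.seed(8)
  pat <- IUPACPattern("TGAY", "TGAY", 0, 2)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    rc <- discChIP:::revcompString(s)
    a <- scanPattern(s, pat)
    b <- scanPattern(rc, pat)
    # mirror each match: start' = L - (start + width - 1) + 1, strand flip
    mirrored <- data.frame(
      start = 80 - (b$start + b$width - 1) + 1,
      width = b$width,
      strand = as.character(ifelse(b$strand == "+", "-", "+")),
      stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand,
                               mirrored$width), ]
    expect_equal(a$start, mirrored$start)
    expect_equal(a$width, mirrored$width)
    expect_equal(a$strand, mirrored$strand)
  }
})

test_that("peak motif fractions hit the planted extremes", {
  sq <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("A", 100), "GGAATG", strrep("A", 94))))
  asm <- GenomeAssembly(c(chr1 = 200), sq)
  pat <- IUPACPattern("GGAATG")
  pkIn <- GRanges("chr1", IRanges(81, 120))
  pkOut <- GRanges("chr1", IRanges(1, 60))
  expect_equal(peakMotifFraction(pkIn, asm, pat)$fraction, 1)
  expect_equal(peakMotifFraction(pkOut, asm, pat)$fraction, 0)
  expect_error(peakMotifFraction(GRanges("chr1", IRanges(150, 300)),
                                 asm, pat), "beyond")
})

test_that("fraction comparison equals exact enumeration", {
  expect_equal(compareFractions(8, 10, 2, 10), 0.02301414,
               tolerance = 1e-6)
  expect_equal(compareFractions(5, 10, 5, 10), 1)
  expect_equal(compareFractions(10, 10, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-9)
  set.seed(4)
  for (i in 1:25) {
    nA <- sample(3:100, 1); nB <- sample(3:100, 1)
    hA <- sample(0:nA, 1); hB <- sample(0:nB, 1)
    p <- compareFractions(hA, nA, hB, nB)
    pOr <- oracleFisherTwoSided(hA, nA - hA, hB, nB - hB)
    expect_lt(abs(p - pOr), 1e-10 + 1e-10 * pOr)
  }
  expect_error(compareFractions(1, 0, 1, 2), "positive")
})

test_that("Hamming distance counts substitutions", {
  expect_equal(countSubstitutions("GACAG", "GGGGG"), 3)
  expect_equal(countSubstitutions("TGAT", "GGGG"), 3)
  expect_equal(countSubstitutions("ACGT", "ACGT"), 0)
  expect_error(countSubstitutions("ACG", "ACGT"), "length")
})

test_that("site mutagenesis removes every targeted match", {
  pat <- IUPACPattern("GACAG")
  s <- paste0("TTT", "GACAG", "TTTTT")
  m <- scanPattern(s, pat, bothStrands = FALSE)
  out <- mutateSites(s, m, "GGGGG")
  expect_equal(out$substitutions, 3)
  expect_equal(nrow(scanPattern(out$sequence, pat, bothStrands = FALSE)), 0)

  # zero sites: unchanged
  none <- mutateSites(s, scanPattern("TTTT", pat, bothStrands = FALSE),
                      "GGGGG")
  expect_equal(none$sequence, s)
  expect_equal(none$substitutions, 0)

  # seven planted sites, all knocked out
  sd <- IUPACPattern("GGAATG")
  s7 <- paste(rep(c("GGAATG", "TTTTTT"), 7), collapse = "")
  m7 <- scanPattern(s7, sd, bothStrands = FALSE)
  expect_equal(nrow(m7), 7)
  out7 <- mutateSites(s7, m7, "CCCCCC")
  expect_equal(nrow(scanPattern(out7$sequence, sd)), 0)
  expect_equal(out7$substitutions, 7 * countSubstitutions("GGAATG", "CCCCCC"))

  expect_error(mutateSites("GACAGACAG",
                           data.frame(start = c(1, 3), width = c(5, 5),
                                      strand = "+"),
                           "GGGGG"), "overlapping")
})

test_that("central enrichment reproduces the closed-form point tail", {
  L <- 100
  seqs <- rep(paste0(strrep("A", 47), "GGAATG", strrep("A", 47)), 100)
  r <- centralEnrichment(seqs, list(Sd = IUPACPattern("GGAATG")),
                         windowWidths = 19, librarySize = 460)
  # all 100 best sites dead-center; window fraction 19/95 = 0.2
  expect_equal(r$countInWindow, 100)
  expect_equal(r$pValue, 0.2^100, tolerance = 1e-9)
  expect_equal(r$eValue, 460 * 0.2^100, tolerance = 1e-9)
  # a single-motif library leaves E = p
  r1 <- centralEnrichment(seqs, list(Sd = IUPACPattern("GGAATG")),
                          windowWidths = 19)
  expect_equal(r1$eValue, r1$pValue)
  expect_error(centralEnrichment(c("AAA", "AAAA"), list(IUPACPattern("A"))),
               "equal length")
})

test_that("PWM scoring picks the best site with central tie-breaks", {
  pwm <- matrix(0.01, nrow = 4, ncol = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["G", ] <- 0.97  # strongly prefers GGGG
  s <- paste0("GGGG", strrep("A", 20), "GGGG", strrep("A", 20), "GGGG")
  # three perfect sites; the middle one is closest to the center
  expect_equal(discChIP:::bestSiteStart(s, pwm), 25)
})

test_that("MEME text motifs parse into probability matrices", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF TEAD1", "letter-probability matrix: alength= 4 w= 2",
               " 0.1 0.2 0.3 0.4", " 0.25 0.25 0.25 0.25",
               "", "MOTIF HTH1", "letter-probability matrix:",
               " 1 0 0 0"), f)
  lib <- readMemeMotifs(f)
  expect_named(lib, c("TEAD1", "HTH1"))
  expect_equal(dim(lib$TEAD1), c(4, 2))
  expect_equal(lib$TEAD1[, 1], c(0.1, 0.2, 0.3, 0.4))
  expect_equal(lib$HTH1[1, 1], 1)
})

test_that("consensus motif lists round-trip", {
  pats <- list(Sd = IUPACPattern("GGAATG", name = "Sd"),
               Hth = IUPACPattern("TGAY", "TGAY", 0, 2, name = "Hth"))
  f <- withr::local_tempfile(fileext = ".txt")
  writeConsensusMotifs(pats, f)
  back <- readConsensusMotifs(f)
  expect_equal(back$Sd@halfSite1, "GGAATG")
  expect_equal(back$Hth@spacerMax, 2L)
  expect_true(isDimer(back$Hth))
  expect_false(isDimer(back$Sd))
})
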