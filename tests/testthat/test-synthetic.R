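test_that("the same seed yields a byte-identical bundle", {
  cfg <- smallGeneratorConfig(seed = 77)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generateBundle(cfg, d1)
  generateBundle(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("degenerate shared fractions produce pure call sets", {
  base <- list(nChroms = 1L, chromLength = 600000L, nHubs = 10L,
               nGenes = 120L, catalogSize = 30L)
  loadTier <- function(dir, f, t, tier)
    readPeaksBed(file.path(dir, sprintf("%s_%s_fdr%d.bed", f, t, tier)))
  classifyBundle <- function(dir, f) {
    classifySpecificity(
      DualTierPeaks(f, "W", loadTier(dir, f, "W", 1),
                    loadTier(dir, f, "W", 25)),
      DualTierPeaks(f, "EA", loadTier(dir, f, "EA", 1),
                    loadTier(dir, f, "EA", 25)))
  }

  cfg0 <- do.call(generatorConfig, c(list(seed = 5, factors = list(
    Sd = list(nPeaks = c(W = 60L, EA = 40L), sharedFraction = 0,
              pattern = "GGAATG"))), base))
  d0 <- file.path(tempdir(), "sf0")
  generateBundle(cfg0, d0)
  cnt0 <- specificityCounts(classifyBundle(d0, "Sd"))
  expect_equal(cnt0$shared, c(0, 0))
  expect_equal(cnt0$specific, c(60, 40))

  cfg1 <- do.call(generatorConfig, c(list(seed = 5, factors = list(
    Sd = list(nPeaks = c(W = 50L, EA = 50L), sharedFraction = 1,
              pattern = "GGAATG"))), base))
  d1 <- file.path(tempdir(), "sf1")
  generateBundle(cfg1, d1)
  cnt1 <- specificityCounts(classifyBundle(d1, "Sd"))
  expect_equal(cnt1$specific, c(0, 0))
  expect_equal(cnt1$shared, c(50, 50))
  unlink(c(d0, d1), recursive = TRUE)
})

test_that("infeasible configurations fail before writing anything", {
  cfg <- generatorConfig(seed = 1, nChroms = 1L, chromLength = 60000L,
                         nHubs = 5L, nGenes = 20L, catalogSize = 5L,
                         factors = list(Sd = list(
                           nPeaks = c(W = 500L, EA = 300L),
                           sharedFraction = 0.5, pattern = NULL)))
  d <- file.path(tempdir(), "infeasible")
  expect_error(generateBundle(cfg, d), "infeasible")
  expect_false(file.exists(file.path(d, "genome.fa")))
  expect_error(generatorConfig(seed = 1, factors = list(Sd = list(
    nPeaks = c(W = 100L, EA = 10L), sharedFraction = 0.5,
    pattern = NULL))), "fewer peaks than shared")
})

test_that("an untampered bundle passes manifest validation", {
  v <- validateManifest(smallBundleDir())
  expect_true(v$pass)
  expect_length(v$failures, 0)
})

test_that("tampering is detected and attributed", {
  src <- smallBundleDir()
  d <- file.path(tempdir(), "tampered")
  unlink(d, recursive = TRUE)
  dir.create(d)
  file.copy(list.files(src, full.names = TRUE), d)

  # break nesting: push the first FDR1 wing peak outside its FDR25 peak
  f <- file.path(d, "Sd_W_fdr1.bed")
  lines <- readLines(f)
  parts <- strsplit(lines[1], "\t")[[1]]
  parts[2] <- as.character(as.integer(parts[2]) + 150000)
  parts[3] <- as.character(as.integer(parts[3]) + 150000)
  writeLines(c(paste(parts, collapse = "\t"), lines[-1]), f)
  v <- validateManifest(d)
  expect_false(v$pass)
  expect_true(any(grepl("Sd/W|class mismatch|state mismatch", v$failures)))

  # restore, then silently mutate a planted motif in the genome
  file.copy(file.path(src, "Sd_W_fdr1.bed"), f, overwrite = TRUE)
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  pk <- as.data.frame(man$peaks)
  hit <- pk[pk$factorName == "Sd" & pk$tier == 1 & pk$motifPlanted, ][1, ]
  asm <- readGenomeFasta(file.path(d, "genome.fa"))
  gr <- GRanges(hit$chrom, IRanges(hit$start + 1L, hit$end))
  s <- discChIP:::peakSequences(gr, asm)
  m <- scanPattern(s, IUPACPattern("GGAATG"))
  mut <- mutateSites(s, m[1, , drop = FALSE], strrep("C", m$width[1]))
  sq <- genomeSequence(asm)
  sq[[hit$chrom]] <- Biostrings::replaceAt(
    sq[[hit$chrom]], IRanges(hit$start + 1L, hit$end),
    Biostrings::DNAStringSet(mut$sequence))
  Biostrings::writeXStringSet(sq, file.path(d, "genome.fa"))
  v2 <- validateManifest(d)
  expect_false(v2$pass)
  expect_true(any(grepl("motif mismatch", v2$failures)))
  unlink(d, recursive = TRUE)
})

test_that("planted rates are realized within sampling error", {
  man <- jsonlite::read_json(file.path(smallBundleDir(), "manifest.json"),
                             simplifyVector = TRUE)
  pk <- as.data.frame(man$peaks)
  sdW <- pk[pk$factorName == "Sd" & pk$tier == 1 & pk$tissue == "W", ]
  expect_equal(nrow(sdW), 100)
  expect_equal(sum(sdW$class == "shared"), 50)
  # state bias: specific peaks lean BLUE-ward relative to shared
  spec <- pk[pk$tier == 1 & pk$class == "specific", ]
  shr <- pk[pk$tier == 1 & pk$class == "shared", ]
  expect_gt(mean(spec$state == "BLUE"), mean(shr$state == "BLUE"))
  expect_gt(mean(shr$state == "YELLOW"), mean(spec$state == "YELLOW"))
})
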