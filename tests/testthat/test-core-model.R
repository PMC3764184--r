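test_that("BED peak round trip preserves coordinates, names and scores", {
  gr <- GRanges("chr2L", IRanges(c(101, 501, 901), c(200, 700, 1100)),
                name = c("pk1", "pk2", "pk3"), score = c(55, 12.5, 7))
  f <- withr::local_tempfile(fileext = ".bed")
  writePeaksBed(gr, f)
  back <- readPeaksBed(f)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(mcols(back)$name, mcols(gr)$name)
  expect_equal(mcols(back)$score, mcols(gr)$score)
  # first line is 0-based half-open on disk
  expect_match(readLines(f)[1], "^chr2L\\t100\\t200\\tpk1\\t55")
})

test_that("BED reader maps fields, skips empties, rejects bad coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2L\t100\t200\tpk1\t55", f)
  gr <- readPeaksBed(f, factorName = "Sd", tissue = "W", fdrTier = 1)
  expect_equal(start(gr), 101)  # 0-based [100,200) -> 1-based [101,200]
  expect_equal(end(gr), 200)
  expect_equal(mcols(gr)$score, 55)
  expect_equal(mcols(gr)$factorName, "Sd")
  expect_equal(mcols(gr)$fdrTier, 1L)

  writeLines(character(0), f)
  expect_length(readPeaksBed(f), 0)

  writeLines("chr2L\t200\t100", f)
  expect_error(readPeaksBed(f))

  writeLines("chr2L\t100\t200", f)
  expect_error(readPeaksBed(f, fdrTier = 5), "fdrTier")
})

test_that("specificity labels travel through the BED name field", {
  gr <- GRanges("chr1", IRanges(c(1, 101), c(50, 200)),
                label = c("SHARED", "SPECIFIC"))
  f <- withr::local_tempfile(fileext = ".bed")
  writePeaksBed(gr, f)
  expect_equal(mcols(readPeaksBed(f))$name, c("SHARED", "SPECIFIC"))
})

test_that("gene model readers derive the TSS from strand", {
  # GFF3 round trip through the package's own writer
  m <- toyGeneModels()
  f <- withr::local_tempfile(fileext = ".gff3")
  writeGeneModelsGff3(m, f)
  back <- readGeneModels(f)
  expect_equal(mcols(geneBodies(back))$gene_id, c("gA", "gB"))
  expect_equal(mcols(geneBodies(back))$tss, c(2001, 7000))
  expect_equal(lengths(geneExons(back)), c(gA = 2L, gB = 2L),
               ignore_attr = TRUE)

  # minus-strand transcript over 0-based [1000,2000) has tss base 1999
  # (1-based 2000); plus-strand tss is base 1000 (1-based 1001)
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t1001\t2000\t.\t-\t.\tID=tm",
               "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=tp"), g)
  mm <- readGeneModels(g)
  expect_equal(mcols(geneBodies(mm))$tss, c(2000, 1001))
})

test_that("BED12 blocks become exons and orphan GFF3 exons error", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 1000, 2000, "tx1", 0, "+", 1000, 2000, "0",
                   2, "200,300", "0,700", sep = "\t"), f)
  m <- readGeneModels(f, format = "bed12")
  ex <- geneExons(m)[[1]]
  expect_length(ex, 2)
  expect_equal(start(ex), c(1001, 1701))
  expect_equal(end(ex), c(1200, 2000))

  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1",
               "chr1\tsrc\texon\t1\t50\t.\t+\t.\tParent=nosuch"), g)
  expect_error(readGeneModels(g), "orphan")
})

test_that("merge collapses overlap chains and preserves covered bases", {
  gr <- GRanges("chr1", IRanges(c(1, 6, 21), c(10, 15, 30)))
  m <- mergeIntervals(gr)
  expect_equal(start(m), c(1, 21))
  expect_equal(end(m), c(15, 30))

  disjoint <- GRanges("chr1", IRanges(c(1, 100), c(10, 120)))
  expect_equal(granges(mergeIntervals(disjoint)), granges(disjoint))

  # positionwise-union oracle on random instances
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:100, 1)
    s <- sample(1:9000, n, replace = TRUE)
    gr <- GRanges(sample(c("c1", "c2"), n, replace = TRUE),
                  IRanges(s, s + sample(1:500, n, replace = TRUE)))
    expect_equal(granges(mergeIntervals(gr)),
                 granges(oracleMergeMask(gr, 10000)))
  }
})

test_that("overlap follows half-open semantics (abutting is disjoint)", {
  a <- GRanges("chr1", IRanges(1, 10))      # BED [0,10)
  b <- GRanges("chr1", IRanges(11, 20))     # BED [10,20)
  expect_false(intervalsOverlap(a, b))
  expect_equal(overlapLength(a, GRanges("chr1", IRanges(10, 20))), 1L)
  expect_equal(overlapLength(a, GRanges("chr1", IRanges(3, 5))), 3L)
  expect_equal(overlapLength(a, GRanges("chr2", IRanges(3, 5))), 0L)
})

test_that("peak centers use the floor convention", {
  # 0-based [0,10) -> center offset 5 -> 1-based base 6
  expect_equal(start(peakCenter(GRanges("c", IRanges(1, 10)))), 6)
  # width-1 interval is its own center
  expect_equal(start(peakCenter(GRanges("c", IRanges(7, 7)))), 7)
})

test_that("coordinates are validated against the assembly", {
  asm <- toyAssembly(1000)
  expect_error(
    discChIP:::validateAgainstAssembly(GRanges("chr1", IRanges(990, 1010)),
                                       asm),
    "beyond")
  expect_error(
    discChIP:::validateAgainstAssembly(GRanges("chrX", IRanges(1, 10)), asm),
    "undeclared")
})

test_that("signal tracks round-trip with gaps preserved as missing", {
  asm <- toyAssembly(5000)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t100\t200\t0.5", "chr1\t300\t400\t0.9"), f)
  tr <- readSignalTrack(f, asm)
  expect_equal(as.numeric(tr$chr1[150]), 0.5)
  expect_true(is.na(as.numeric(tr$chr1[250])))
  f2 <- withr::local_tempfile(fileext = ".bedGraph")
  writeSignalTrack(tr, f2)
  expect_equal(readLines(f2), readLines(f))
})

test_that("fixed-step wiggle tracks load like bedGraph", {
  asm <- toyAssembly(2000)
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=101 step=1",
               as.character(c(0.1, 0.2, 0.3))), f)
  tr <- readSignalTrack(f, asm)
  expect_equal(as.numeric(tr$chr1[101:103]), c(0.1, 0.2, 0.3))
  expect_true(is.na(as.numeric(tr$chr1[104])))
})

test_that("enhancer catalog and GMT round-trip", {
  gr <- GRanges("chr1", IRanges(c(1, 1001), c(500, 1500)))
  mcols(gr)$id <- c("E1", "E2")
  for (tis in c("eye", "antenna", "leg", "wing"))
    mcols(gr)[[tis]] <- c(TRUE, FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEnhancerCatalog(gr, f)
  back <- readEnhancerCatalog(f)
  expect_equal(granges(back), granges(gr))
  expect_equal(mcols(back)$wing, c(TRUE, FALSE))
  expect_error(readEnhancerCatalog({
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines("id\tchrom\tstart\tend\teye", f2); f2
  }), "missing column")

  sets <- list(s1 = c("g1", "g2"), s2 = c("g3"))
  g <- withr::local_tempfile(fileext = ".gmt")
  writeGeneSets(sets, g)
  expect_equal(readGeneSets(g), sets)
})

test_that("segmentation reader enforces the five-state alphabet", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tYELLOW", "chr1\t100\t300\tBLUE"), f)
  seg <- readSegmentationBed(f)
  expect_equal(as.character(mcols(seg)$state), c("YELLOW", "BLUE"))
  writeLines("chr1\t0\t100\tMAUVE", f)
  expect_error(readSegmentationBed(f), "MAUVE")
  writeLines(c("chr1\t0\t100\tYELLOW", "chr1\t50\t300\tBLUE"), f)
  expect_error(readSegmentationBed(f), "overlap")
})
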