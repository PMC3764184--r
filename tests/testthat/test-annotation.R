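test_that("region labels follow the strand-aware promoter window", {
  m <- toyGeneModels()  # gA: + strand, tss 2001; gB: - strand, tss 7000
  # center 1301 lies within 1 kb upstream of gA's TSS
  expect_equal(as.character(assignRegion(
    GRanges("chr1", IRanges(1201, 1400)), m)), "PROMOTER")
  # center within 1 kb downstream-of-coordinate of gB's TSS (its upstream)
  expect_equal(as.character(assignRegion(
    GRanges("chr1", IRanges(7101, 7300)), m)), "PROMOTER")
  # inside gA's first exon
  expect_equal(as.character(assignRegion(
    GRanges("chr1", IRanges(2101, 2200)), m)), "EXON")
  # inside gA's intron
  expect_equal(as.character(assignRegion(
    GRanges("chr1", IRanges(2401, 2600)), m)), "INTRON")
  # a desert
  expect_equal(as.character(assignRegion(
    GRanges("chr1", IRanges(12001, 12200)), m)), "INTERGENIC")
})

test_that("promoter precedence beats exon at overlapping annotations", {
  # one gene's exon covers the center; another gene's TSS is < 1 kb away
  bodies <- GRanges("chr1", IRanges(c(1001, 2501), c(2000, 3500)),
                    strand = c("+", "+"))
  exons <- GRangesList(
    GRanges("chr1", IRanges(1001, 2000), strand = "+"),
    GRanges("chr1", IRanges(2501, 3500), strand = "+"))
  m <- discChIP:::makeGeneModels(bodies, c("gX", "gY"), exons)
  # center 1900: inside gX exon AND within [1501,2500) upstream of gY
  expect_equal(as.character(assignRegion(
    GRanges("chr1", IRanges(1801, 2000)), m)), "PROMOTER")
})

test_that("precedence agrees with an exhaustive small-genome oracle", {
  m <- toyGeneModels()
  prom <- promoters(geneTss(m), upstream = 1000, downstream = 0)
  exons <- unlist(geneExons(m))
  bodies <- geneBodies(m)
  centers <- seq(1, 9000, by = 37)
  pk <- GRanges("chr1", IRanges(centers, centers))
  got <- as.character(assignRegion(pk, m))
  oracle <- vapply(centers, function(p) {
    pt <- GRanges("chr1", IRanges(p, p))
    if (any(overlapsAny(pt, prom, ignore.strand = TRUE))) "PROMOTER"
    else if (any(overlapsAny(pt, exons, ignore.strand = TRUE))) "EXON"
    else if (any(overlapsAny(pt, bodies, ignore.strand = TRUE))) "INTRON"
    else "INTERGENIC"
  }, "")
  expect_equal(got, oracle)
})

test_that("region breakdown is an exact partition", {
  m <- toyGeneModels()
  pk <- GRanges("chr1", IRanges(c(1201, 7101, 12001, 15001), width = 200))
  bd <- regionBreakdown(pk, m)
  expect_equal(sum(bd), 1, tolerance = 1e-12)
  expect_equal(as.numeric(bd["PROMOTER"]), 0.5)
  expect_equal(as.numeric(bd["INTERGENIC"]), 0.5)
  expect_error(regionBreakdown(GRanges(), m), ">= 1 peak")
})

test_that("gene logic classes partition targeted genes exactly", {
  m <- toyGeneModels()
  calls <- GRanges("chr1", IRanges(c(2101, 2501, 6101), width = 100),
                   label = c("SHARED", "SPECIFIC", "SHARED"))
  tg <- assignTargets(calls, m, maxDistance = 1000)
  expect_equal(tg$logicClass[tg$gene_id == "gA"], "SHARED_PLUS_SPECIFIC")
  expect_equal(tg$logicClass[tg$gene_id == "gB"], "SHARED_ONLY")

  # random fixtures: classes equal brute-force recomputation
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    starts <- sample(1:19000, n)
    calls <- GRanges("chr1", IRanges(starts, width = 150),
                     label = sample(c("SHARED", "SPECIFIC"), n, TRUE))
    tg <- assignTargets(calls, m, maxDistance = 2000)
    for (g in seq_along(geneBodies(m))) {
      gid <- mcols(geneBodies(m))$gene_id[g]
      body <- geneBodies(m)[g]
      tpos <- mcols(geneBodies(m))$tss[g]
      twin <- GRanges("chr1", IRanges(max(1, tpos - 2000), tpos + 2000))
      targeting <- overlapsAny(calls, body, ignore.strand = TRUE) |
        overlapsAny(calls, twin)
      labs <- mcols(calls)$label[targeting]
      if (!length(labs)) {
        expect_false(gid %in% tg$gene_id)
      } else {
        want <- if (all(labs == "SHARED")) "SHARED_ONLY"
                else if (all(labs == "SPECIFIC")) "SPECIFIC_ONLY"
                else "SHARED_PLUS_SPECIFIC"
        expect_equal(tg$logicClass[tg$gene_id == gid], want)
      }
    }
    expect_setequal(tg$logicClass,
                    intersect(c("SHARED_ONLY", "SPECIFIC_ONLY",
                                "SHARED_PLUS_SPECIFIC"), tg$logicClass))
  }
})

test_that("gene-set enrichment matches the exact tail and saturates", {
  universe <- paste0("g", 1:100)
  sets <- list(s = universe[1:10])
  lst <- c(universe[1:5], universe[50:54])  # 5 hits, list of 10
  r <- geneSetEnrichment(lst, universe, sets)
  pOracle <- oracleHyperTail(100, 10, 10, 5)
  expect_lt(abs(r$pValue - pOracle) / pOracle, 1e-10)
  expect_equal(r$pValue, 6.7162775e-04, tolerance = 1e-6)

  # no hits -> p ~ 1
  r0 <- geneSetEnrichment(universe[50:59], universe, sets)
  expect_gt(r0$pValue, 0.65)
  # list = universe -> every set saturated, p = 1
  rAll <- geneSetEnrichment(universe, universe, sets)
  expect_equal(rAll$pValue, 1)
  expect_error(geneSetEnrichment("zzz", universe, sets), "outside")
  expect_error(geneSetEnrichment("g1", character(0), sets), "empty universe")
})

test_that("BH adjustment equals the textbook step-up on random p vectors", {
  universe <- paste0("g", 1:200)
  set.seed(99)
  sets <- lapply(1:15, function(i) sample(universe, 25))
  names(sets) <- paste0("s", 1:15)
  r <- geneSetEnrichment(sample(universe, 30), universe, sets)
  expect_equal(r$bhFdr, oracleBH(r$pValue))
  expect_true(all(r$bhFdr >= r$pValue - 1e-12))
})
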