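mkCatalog <- function(chrom, start, end, id, len = 1000, sg = "A") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  names(gr) <- id
  S4Vectors::mcols(gr)$subgenome <- sg
  S4Vectors::mcols(gr)$transcript_length <- len
  gr
}

he2A <- function() {
  gr <- GenomicRanges::GRanges("Chr2A", IRanges::IRanges(8e5 + 1, 51.8e6))
  S4Vectors::mcols(gr)$line <- "X190"
  S4Vectors::mcols(gr)$multiplier <- 2
  gr
}

test_that("HE-region and scaffold genes are excluded, others retained", {
  cat <- mkCatalog(c("Chr2A", "Chr2A", "unplaced"),
                   c(30e6, 60e6, 1), c(30.002e6, 60.002e6, 1000),
                   c("inHE", "outside", "scaffold"))
  res <- excludeHEGenes(cat, he2A())
  expect_setequal(res$removed, c("inHE", "scaffold"))
  expect_identical(res$kept, "outside")
  expect_equal(res$report$removed[res$report$rule == "he_region"], 1)
  expect_equal(res$report$removed[res$report$rule == "unplaced_scaffold"], 1)

  # one-bp overlap suffices
  border <- mkCatalog("Chr2A", 51.8e6, 51.9e6, "edge")
  expect_identical(excludeHEGenes(border, he2A())$removed, "edge")
  clear <- mkCatalog("Chr2A", 51.8e6 + 1, 51.9e6, "clear")
  expect_length(excludeHEGenes(clear, he2A())$removed, 0)

  weird <- GenomicRanges::GRanges("ChrZZ", IRanges::IRanges(1, 10))
  S4Vectors::mcols(weird)$line <- "X190"
  S4Vectors::mcols(weird)$multiplier <- 0
  expect_error(excludeHEGenes(cat, weird), "unknown chromosome")
})

test_that("mean-count window keeps [10, 5000] inclusively", {
  m <- rbind(const9 = rep(9L, 4), const10 = rep(10L, 4),
             mixed = c(0L, 30L, 0L, 30L), const5000 = rep(5000L, 4),
             high = rep(5001L, 4))
  expect_setequal(filterByMeanCount(m), c("const10", "mixed", "const5000"))
  expect_error(filterByMeanCount(m[0, , drop = FALSE]), "empty")
})

test_that("length disparity uses the longer transcript as denominator", {
  cat <- suppressWarnings(c(
    mkCatalog("Chr1A", c(1, 100, 200), c(50, 150, 250),
              c("a1", "a2", "a3"), len = c(1000, 1000, 1000)),
    mkCatalog("Chr1D", c(1, 100, 200), c(50, 150, 250),
              c("d1", "d2", "d3"), len = c(1100, 1000, 1200), sg = "D")))
  hp <- HomoeologPairs(c("a1", "a2", "a3"), c("d1", "d2", "d3"))
  out <- filterPairsByLength(hp, cat)
  # 100/1100 = 9.09% keep; 0% keep; 200/1200 = 16.7% drop
  expect_identical(out@pairs$lengthOK, c(TRUE, TRUE, FALSE))

  expect_error(filterPairsByLength(HomoeologPairs("a1", "dX"), cat),
               "missing transcript length")
})

test_that("a pair needs one expressed copy to stay analyzed", {
  m <- rbind(a1 = rep(50L, 4), d1 = rep(0L, 4),
             a2 = rep(0L, 4), d2 = rep(0L, 4))
  hp <- HomoeologPairs(c("a1", "a2"), c("d1", "d2"))
  out <- filterPairsByExpression(hp, m)
  expect_identical(out@pairs$expressed, c(TRUE, FALSE))
})

test_that("filters are idempotent and HE/mean-count order-free", {
  std <- smallStudy()
  m <- studyCounts(std)
  cat <- std$catalog
  he <- std$heRegions

  f1 <- excludeHEGenes(cat, he)
  f2 <- excludeHEGenes(cat[f1$kept], he)
  expect_identical(sort(f1$kept), sort(f2$kept))

  # HE exclusion commutes with the mean-count window
  a <- filterByMeanCount(m[f1$kept, ])
  b <- intersect(filterByMeanCount(m), f1$kept)
  expect_setequal(a, b)

  expect_setequal(filterByMeanCount(m[a, ]), a)
})

test_that("pair filter tallies match the planted truth exactly", {
  std <- smallStudy()
  cfg <- std$config
  m <- studyCounts(std)
  pairs <- filterPairs(std$pairs, std$catalog, std$heRegions, m)
  pt <- pairs@pairs

  # length rule: planted violation count is exact
  expect_equal(sum(!pt$lengthOK),
               round(cfg@lengthDisparityFraction * cfg@nPairs))

  # HE rule recomputed from interval overlap of either copy
  drop <- names(std$catalog)[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(std$catalog, std$heRegions))]
  expect_equal(sum(!pt$heOK),
               sum(pt$aGene %in% drop | pt$dGene %in% drop))

  # expression rule recomputed from raw means
  mA <- rowMeans(m)[pt$aGene]
  mD <- rowMeans(m)[pt$dGene]
  expect_identical(unname(pt$expressed), unname(mA >= 10 | mD >= 10))

  expect_identical(pt$analyzed, pt$heOK & pt$lengthOK & pt$expressed)

  # gene-level report partitions are exact
  fg <- filterGenes(std$catalog, std$heRegions, m)
  expect_equal(length(std$catalog) - sum(fg$report$removed),
               length(fg$expressed))
})
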