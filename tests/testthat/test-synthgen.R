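test_that("catalog sizes follow the configuration", {
  cfg <- simConfig(nPairs = 50, nSingletonA = 0, nSingletonD = 0,
                   nScaffoldA = 0, nScaffoldD = 0, seed = 3)
  cat <- generateCatalog(cfg)
  expect_length(cat$catalogA, 50)
  expect_length(cat$catalogD, 50)
  expect_equal(nPairs(cat$pairs), 50)
  pt <- pairTable(cat$pairs)
  expect_true(all(pt$aGene %in% names(cat$catalogA)))
  expect_true(all(pt$dGene %in% names(cat$catalogD)))

  cat2 <- generateCatalog(smallConfig())
  expect_length(cat2$catalogA, 200 + 80 + 10)
  expect_equal(sum(GenomicRanges::seqnames(cat2$catalogA) == "unplaced"), 10)
})

test_that("default HE intervals cover the terminal exchange geometry", {
  he <- defaultHERegions()
  expect_setequal(he$chrom, c("Chr2A", "Chr2D", "Chr3A", "Chr3D"))
  expect_equal(he$start[he$chrom == "Chr2A"], 8e5)
  expect_equal(he$end[he$chrom == "Chr2A"], 51.8e6)
  expect_equal(he$start[he$chrom == "Chr2D"], 4e5)
  expect_equal(he$end[he$chrom == "Chr2D"], 58e6)
  expect_equal(he$start[he$chrom == "Chr3A"], 684.6e6)
  expect_equal(he$start[he$chrom == "Chr3D"], 557.4e6)
  # duplicated copy gains, deleted copy vanishes
  expect_equal(he$multiplier[he$chrom %in% c("Chr2A", "Chr3A")], c(2, 2))
  expect_equal(he$multiplier[he$chrom %in% c("Chr2D", "Chr3D")], c(0, 0))
  std <- smallStudy()
  hit <- GenomicRanges::findOverlaps(std$catalog, std$heRegions)
  expect_gt(length(hit), 0)  # some genes do fall inside HE regions
})

test_that("length-disparity planting is exact under the deterministic assignment", {
  cfg <- simConfig(nPairs = 1000, nSingletonA = 0, nSingletonD = 0,
                   nScaffoldA = 0, nScaffoldD = 0,
                   lengthDisparityFraction = 0.2, seed = 5)
  cat <- generateCatalog(cfg)
  flt <- filterPairsByLength(cat$pairs, cat$catalog)
  expect_equal(sum(!flt@pairs$lengthOK), 200)
})

test_that("identical config and seed give byte-identical study files", {
  cfg <- simConfig(nPairs = 60, nScaffoldA = 5, nScaffoldD = 5, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeStudy(simulateHomoeoStudy(cfg), d1)
  writeStudy(simulateHomoeoStudy(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("Mix samples expect half the pure-parent rate", {
  cfg <- simConfig(nPairs = 150, nSingletonA = 0, nSingletonD = 0,
                   nScaffoldA = 0, nScaffoldD = 0, replicates = 20,
                   libSizeRange = c(1, 1), dispersion = 0.02,
                   conditions = "mock-2d",
                   modeProportions = matrix(c(0, 0, 1, 0, 0, 0, 0, 0, 0),
                                            1, 9,
                                            dimnames = list("mock-2d", NULL)),
                   seed = 21)
  std <- simulateHomoeoStudy(cfg)
  m <- studyCounts(std)
  aGenes <- names(std$catalogA)
  mix <- rowMeans(m[aGenes, grep("^Mix_", colnames(m)), drop = FALSE])
  par <- rowMeans(m[aGenes, grep("^parentA_", colnames(m)), drop = FALSE])
  ratio <- mix / par
  expect_gt(mean(abs(ratio - 0.5) < 0.15), 0.95)
  expect_lt(abs(mean(ratio) - 0.5), 0.05)
})

test_that("zero dispersion degenerates to Poisson counts", {
  cfg <- simConfig(nPairs = 100, nSingletonA = 0, nSingletonD = 0,
                   nScaffoldA = 0, nScaffoldD = 0, replicates = 30,
                   dispersion = 0, libSizeRange = c(1, 1), seed = 8)
  std <- simulateHomoeoStudy(cfg)
  m <- studyCounts(std)
  mixCols <- grep("^Mix_mock-2d", colnames(m))
  v <- apply(m[, mixCols], 1, var)
  mu <- rowMeans(m[, mixCols])
  # variance tracks the mean; under NB with alpha = 0.05 the median
  # variance/mean ratio would sit near 1 + alpha * mu >> 1 here
  expect_lt(abs(median(v / pmax(mu, 1)) - 1), 0.2)
})

test_that("planted progeny fold is recovered in group means", {
  # all pairs conserved A>D with fold 4: over many pairs the ratio of EUP
  # A-copy to D-copy means approaches 4
  cfg <- simConfig(nPairs = 1000, nSingletonA = 0, nSingletonD = 0,
                   nScaffoldA = 0, nScaffoldD = 0, replicates = 3,
                   libSizeRange = c(1, 1), conditions = "mock-2d",
                   modeProportions = matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0),
                                            1, 9,
                                            dimnames = list("mock-2d", NULL)),
                   seed = 13)
  std <- simulateHomoeoStudy(cfg)
  m <- studyCounts(std)
  pt <- pairTable(std$pairs)
  eup <- grep("^EUP_", colnames(m))
  ratio <- rowMeans(m[pt$aGene, eup]) / pmax(rowMeans(m[pt$dGene, eup]), 1)
  expect_lt(abs(mean(ratio) - 4), 0.4)
})

test_that("HE copy-number multipliers act only on X190", {
  std <- smallStudy()
  m <- studyCounts(std)
  del <- names(std$catalog)[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(std$catalog, std$heRegions[
      S4Vectors::mcols(std$heRegions)$multiplier == 0]))]
  expect_gt(length(del), 0)
  x190 <- grep("^X190_", colnames(m))
  eup <- grep("^EUP_", colnames(m))
  expect_true(all(m[del, x190] == 0))
  expect_gt(sum(m[del, eup]), 0)
  dup <- names(std$catalog)[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(std$catalog, std$heRegions[
      S4Vectors::mcols(std$heRegions)$multiplier == 2]))]
  expect_gt(mean(m[dup, x190]) / mean(m[dup, eup]), 1.5)
})

test_that("planted mode proportions are recovered within multinomial error", {
  cfg <- simConfig(nPairs = 2000, nSingletonA = 0, nSingletonD = 0,
                   nScaffoldA = 0, nScaffoldD = 0, seed = 31)
  cat <- generateCatalog(cfg)
  tr <- planTruth(cfg, cat)
  pt <- pairTruth(tr)
  for (cond in cfg@conditions) {
    phat <- tabulate(pt$mode[pt$condition == cond], 9) / 2000
    expect_lt(max(abs(phat - cfg@modeProportions[cond, ])), 0.05)
  }
})

test_that("a non-enriched GO term behaves as background", {
  # with odds ratio 1 the designated term carries no signal: its
  # enrichment p across seeds is not systematically small
  low <- 0
  reps <- 60
  for (s in seq_len(reps)) {
    cfg <- simConfig(nPairs = 100, nSingletonA = 50, nSingletonD = 50,
                     nScaffoldA = 0, nScaffoldD = 0, goTerms = 15,
                     goEnrichedOR = 1, seed = 4000 + s)
    cat <- generateCatalog(cfg)
    tr <- planTruth(cfg, cat)
    gm <- generateGOMap(cfg, tr, cat)
    changed <- rownames(tr@progenyMult)[tr@progenyMult[, 1] != 1]
    er <- enrichTerms(changed, names(cat$catalog), gm)
    pv <- er$pvalue[er$term == attr(gm, "enrichedTerm")]
    if (length(pv) && pv < 0.05) low <- low + 1
  }
  expect_lte(low / reps, 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nPairs = 100, seed = 1, replicates = 1),
               "replicates")
  expect_error(simConfig(nPairs = 100, seed = 1, dispersion = -1),
               "dispersion")
  expect_error(simConfig(nPairs = 100), "seed")
  expect_error(simConfig(nPairs = 1e7, seed = 1), "placeable")
  he <- defaultHERegions()
  he$multiplier[1] <- -2
  expect_error(simConfig(nPairs = 100, seed = 1, heRegions = he),
               "non-negative")
})
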