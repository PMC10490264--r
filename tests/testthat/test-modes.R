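test_that("classifyMode matches the exhaustive 3x3 truth table", {
  expected <- list(
    list("A>D", "A>D", 1L, "conserved"),
    list("A<D", "A<D", 2L, "conserved"),
    list("A=D", "A=D", 3L, "conserved"),
    list("A>D", "A=D", 4L, "convergent"),
    list("A<D", "A=D", 5L, "convergent"),
    list("A=D", "A>D", 6L, "divergent"),
    list("A=D", "A<D", 7L, "divergent"),
    list("A>D", "A<D", 8L, "reversed"),
    list("A<D", "A>D", 9L, "reversed"))
  for (e in expected) {
    cl <- classifyMode(e[[1]], e[[2]])
    expect_equal(cl$mode, e[[3]], label = paste(e[[1]], e[[2]]))
    expect_equal(cl$regulation, e[[4]])
  }
  # total on the 3x3 domain, injective
  grid <- expand.grid(p = c("A>D", "A<D", "A=D"),
                      g = c("A>D", "A<D", "A=D"),
                      stringsAsFactors = FALSE)
  all9 <- classifyMode(grid$p, grid$g)$mode
  expect_setequal(all9, 1:9)
  expect_error(classifyMode("A>>D", "A=D"), "invalid ratio call")
})

test_that("mode-count summaries reproduce percentages and subtotals", {
  s <- summarizeModeCounts(c(360, 357, 2645, 425, 279, 136, 204, 11, 3))
  expect_equal(s$total, 4420)
  expect_equal(s$modes$pct[1], 8.14)
  expect_equal(s$regulation$count[s$regulation$regulation == "conserved"],
               3362)
  expect_equal(s$regulation$pct[s$regulation$regulation == "conserved"],
               76.06)
  expect_equal(sum(s$modes$count), s$total)
  expect_lt(abs(sum(s$modes$pct) - 100), 0.05)

  z <- summarizeModeCounts(rep(0, 9))
  expect_equal(z$total, 0)
  expect_true(all(z$modes$pct == 0))

  empty <- summarizeModes(data.frame(mode = integer(),
                                     pairId = character()))
  expect_equal(nrow(empty), 0)
})

test_that("null pairs are called mode 3 and planted modes are recovered", {
  cfg <- simConfig(nPairs = 400, nSingletonA = 0, nSingletonD = 0,
                   nScaffoldA = 0, nScaffoldD = 0, conditions = "mock-2d",
                   heRegions = defaultHERegions()[0, ],
                   modeProportions = matrix(c(0, 0, 1, 0, 0, 0, 0, 0, 0),
                                            1, 9,
                                            dimnames = list("mock-2d", NULL)),
                   seed = 19)
  std <- simulateHomoeoStudy(cfg)
  deP <- compareHomoeologs(std$experiment, std$pairs, "Mix", "mock-2d")
  deG <- compareHomoeologs(std$experiment, std$pairs, "EUP", "mock-2d")
  mc <- callModes(std$pairs, deP, deG)
  expect_gt(mean(mc$mode == 3), 0.95)
  expect_equal(sum(tabulate(mc$mode, 9)), nPairs(std$pairs))
})

test_that("mode calls recover the planted modes of the default fixture", {
  std <- smallStudy()
  hex <- std$experiment
  m <- studyCounts(std)
  pairs <- filterPairs(std$pairs, std$catalog, std$heRegions, m)
  d <- designInfo(hex)
  use <- d$sample[d$genotype %in% c("Mix", "EUP", "X190")]
  sf <- computeSizeFactors(m[, use])
  deP <- compareHomoeologs(hex, pairs, "Mix", "mock-2d", sizeFactors = sf)
  deG <- compareHomoeologs(hex, pairs, "EUP", "mock-2d", sizeFactors = sf)
  mc <- callModes(pairs, deP, deG)
  tr <- pairTruth(std$truth)
  tr <- tr[tr$condition == "mock-2d", ]
  mm <- merge(mc, tr, by = "pairId")
  expect_gt(mean(mm$mode.x == mm$mode.y), 0.9)

  # missing pair -> consistency error
  expect_error(callModes(pairs, deP[-1, ], deG), "missing from")
})

test_that("per-copy attribution labels follow the padj threshold", {
  mc <- data.frame(pairId = c("p1", "p2"), mode = c(4L, 3L))
  deA <- S4Vectors::DataFrame(log2FoldChange = c(2, 0.5),
                              padj = c(0.01, 0.8),
                              row.names = c("a1", "a2"))
  deD <- S4Vectors::DataFrame(log2FoldChange = c(-0.2, -3),
                              padj = c(0.8, 0.6),
                              row.names = c("d1", "d2"))
  att <- attributeModeChanges(mc, deA, deD, c("a1", "a2"), c("d1", "d2"))
  expect_identical(att$labels$aChange, c("up", "unchanged"))
  expect_identical(att$labels$dChange, c("unchanged", "unchanged"))
  expect_equal(sum(att$crossTab), 2)

  # on the fixture, one-copy changes dominate convergent/divergent pairs
  std <- smallStudy()
  tr <- pairTruth(std$truth)
  cd <- tr[tr$mode %in% 4:7, ]
  oneCopy <- xor(cd$deltaA == "unchanged", cd$deltaD == "unchanged")
  expect_true(all(oneCopy))
})

test_that("swapping subgenome labels permutes modes 1<->2, 4<->5, 6<->7, 8<->9", {
  std <- smallStudy()
  hex <- std$experiment
  m <- studyCounts(std)
  pairs <- filterPairs(std$pairs, std$catalog, std$heRegions, m)
  d <- designInfo(hex)
  use <- d$sample[d$genotype %in% c("Mix", "EUP")]
  sf <- computeSizeFactors(m[, use])

  pt <- pairs@pairs
  swapped <- HomoeologPairs(pt$dGene, pt$aGene, pairId = pt$pairId)
  swapped@pairs$analyzed <- pt$analyzed

  mc <- callModes(pairs,
                  compareHomoeologs(hex, pairs, "Mix", "mock-2d", sf),
                  compareHomoeologs(hex, pairs, "EUP", "mock-2d", sf))
  ms <- callModes(swapped,
                  compareHomoeologs(hex, swapped, "Mix", "mock-2d", sf),
                  compareHomoeologs(hex, swapped, "EUP", "mock-2d", sf))
  map <- c(2L, 1L, 3L, 5L, 4L, 7L, 6L, 9L, 8L)
  expect_identical(ms$mode, map[mc$mode])
})
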