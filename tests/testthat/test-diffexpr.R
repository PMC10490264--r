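test_that("size factors obey the median-of-ratios contract", {
  set.seed(1)
  base <- matrix(rpois(400, 100), 100, 4,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))

  # identical samples -> unit factors
  two <- base[, c(1, 1)]
  colnames(two) <- c("s1", "s2")
  expect_equal(unname(computeSizeFactors(two)), c(1, 1))

  # exact doubling -> factor ratio 2:1
  dbl <- cbind(s1 = base[, 1], s2 = 2L * base[, 1])
  sf <- computeSizeFactors(dbl)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # scaling one sample scales its factor relative to all others by c
  # (the geometric-mean reference absorbs c^(1/n))
  sf0 <- computeSizeFactors(base)
  scaled <- base
  scaled[, 3] <- scaled[, 3] * 10L
  sf1 <- computeSizeFactors(scaled)
  rel0 <- sf0 / sf0[1]
  rel1 <- sf1 / sf1[1]
  expect_equal(unname(rel1[3] / rel0[3]), 10, tolerance = 1e-12)
  expect_equal(unname(rel1[-3]), unname(rel0[-3]), tolerance = 1e-12)

  # all-zero gene rows alone cannot support normalization
  z <- matrix(0L, 5, 3, dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  z[1, 1] <- 10L
  expect_error(computeSizeFactors(z), "normalization error")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(1500, size = 10, mu = 150), 250, 6,
              dimnames = list(paste0("g", 1:250), paste0("s", 1:6)))
  m[, 4] <- m[, 4] * 3L
  expect_equal(unname(computeSizeFactors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("dispersion estimation is calibrated", {
  set.seed(7)
  n <- 300
  mu <- exp(runif(n, log(50), log(1000)))
  # Poisson data, 50 replicates per group -> dispersion collapses
  mP <- matrix(rpois(n * 100, rep(mu, 100)), n, 100,
               dimnames = list(paste0("g", 1:n), NULL))
  dP <- computeDispersions(mP, rep(c("a", "b"), each = 50))
  expect_lt(median(dP), 0.01)

  # NB at alpha = 0.1 -> estimates concentrate around the truth
  mN <- matrix(rnbinom(n * 100, size = 10, mu = rep(mu, 100)), n, 100,
               dimnames = list(paste0("g", 1:n), NULL))
  dN <- computeDispersions(mN, rep(c("a", "b"), each = 50))
  expect_gt(mean(dN >= 0.05 & dN <= 0.2), 0.9)

  # constant counts -> floor
  mC <- matrix(7L, 5, 6, dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(unname(computeDispersions(mC, rep(c("a", "b"), each = 3),
                                         sizeFactors = rep(1, 6),
                                         shrink = FALSE)),
               rep(1e-8, 5))

  expect_error(computeDispersions(mC[, 1:2], c("a", "b")),
               "estimation error")
})

test_that("the Wald test is exact at the null point and label-symmetric", {
  m <- matrix(rep(c(100L, 200L, 300L), 2), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  res <- nbWaldTest(m, 1:3, 4:6, sizeFactors = rep(1, 6),
                    dispersions = 0.05)
  expect_equal(res$log2FoldChange, 0)
  expect_equal(res$pvalue, 1)

  set.seed(9)
  mm <- matrix(rnbinom(600, size = 20, mu = 200), 100, 6,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  a <- nbWaldTest(mm, 1:3, 4:6)
  b <- nbWaldTest(mm, 4:6, 1:3)
  expect_equal(a$log2FoldChange, -b$log2FoldChange, tolerance = 1e-12)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)

  expect_error(nbWaldTest(mm, integer(0), 4:6), "empty group")
  expect_error(nbWaldTest(mm, 1:3, 3:6), "disjoint")
})

test_that("null p-values are approximately uniform", {
  set.seed(11)
  n <- 5000
  mu <- exp(runif(n, log(50), log(1500)))
  m <- matrix(rnbinom(n * 6, size = 20, mu = rep(mu, 6)), n, 6,
              dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
  res <- nbWaldTest(m, 1:3, 4:6)
  ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(bhAdjust(0.33), 0.33)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.1, NA)), "\\[0, 1\\]")
  # monotone in p-rank
  set.seed(3)
  p <- runif(50)
  adj <- bhAdjust(p)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("DEG calls use strict padj < alpha and carry direction", {
  res <- S4Vectors::DataFrame(
    baseMean = c(10, 10, 10), log2FoldChange = c(-1, 2, 1),
    lfcSE = 1, stat = 0, pvalue = c(0.01, 0.02, 0.04),
    padj = c(0.049, 0.05, 0.2),
    row.names = c("g1", "g2", "g3"))
  degs <- callDEGs(res)
  expect_identical(degs$unit, "g1")
  expect_identical(degs$direction, "down")
})
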