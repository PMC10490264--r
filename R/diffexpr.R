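# Negative binomial two-group differential expression: median-of-ratios
# size factors, moment-based dispersion with shrinkage toward a parametric
# mean-dispersion trend, and a Wald test on the log ratio of group means
# with standard errors from the NB Fisher information.

#' Median-of-ratios size factors
#'
#' factor_s = median over genes g (with nonzero geometric mean) of
#' count_{g,s} / geomean_g. Scaling one sample's counts by c scales its
#' factor relative to every other sample's by c (the geometric-mean
#' reference shifts, so relative factors carry the normalization contract,
#' as in DESeq2).
#'
#' @param counts integer matrix (genes x samples).
#' @return numeric vector of positive factors, one per sample.
#' @examples
#' m <- matrix(rpois(200, 50), 50, 4)
#' rownames(m) <- paste0("g", 1:50)
#' computeSizeFactors(m)
#' @export
computeSizeFactors <- function(counts) {
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    stopf("normalization error: no gene has nonzero counts in every sample")
  lc <- log(counts[use, , drop = FALSE])
  sf <- apply(lc, 2, function(x) exp(stats::median(x - logGeo[use])))
  names(sf) <- colnames(counts)
  sf
}

#' Moment-based NB dispersion with trend shrinkage
#'
#' Per unit (gene or homoeolog pair), a method-of-moments estimate of the
#' dispersion alpha in Var = mu + alpha mu^2 is computed on normalized
#' counts pooled within groups, then shrunk toward a parametric
#' mean-dispersion trend alpha(mu) = a0 + a1/mu fitted across units
#' (arithmetic combination weighted by residual vs prior degrees of
#' freedom). Estimates are floored at 1e-8.
#'
#' @param counts integer matrix (units x samples).
#' @param groups factor/character of length ncol(counts).
#' @param sizeFactors optional size factors (computed if NULL).
#' @param shrink shrink toward the fitted trend (default TRUE).
#' @param priorWeight prior degrees of freedom for the trend (default 10).
#' @return numeric vector of dispersions, one per unit.
#' @export
computeDispersions <- function(counts, groups, sizeFactors = NULL,
                               shrink = TRUE, priorWeight = 10) {
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stopf("groups must have one entry per sample")
  nper <- table(groups)
  dfResid <- ncol(counts) - length(nper)
  if (dfResid <= 0)
    stopf("estimation error: need replicates in at least one group")
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  q <- sweep(counts, 2, sizeFactors, "/")
  xim <- mean(1 / sizeFactors)

  ss <- 0
  mu <- 0
  for (g in names(nper)) {
    cols <- groups == g
    gm <- rowMeans(q[, cols, drop = FALSE])
    ss <- ss + rowSums((q[, cols, drop = FALSE] - gm)^2)
    mu <- mu + gm * nper[[g]]
  }
  mu <- mu / ncol(counts)
  pooledVar <- ss / dfResid
  raw <- ifelse(mu > 0, (pooledVar - xim * mu) / mu^2, 0)

  if (!shrink)
    return(pmax(raw, 1e-8))

  trend <- .fitDispersionTrend(raw, mu)
  alphaTrend <- pmax(trend$a0 + trend$a1 / pmax(mu, 1e-8), 1e-8)
  shrunk <- (dfResid * pmax(raw, 0) + priorWeight * alphaTrend) /
    (dfResid + priorWeight)
  pmax(shrunk, 1e-8)
}

# parametric trend alpha(mu) = a0 + a1/mu, gamma-family GLM as used for
# mean-dispersion trends in NB count models; falls back to a flat median
# trend if the fit degenerates
.fitDispersionTrend <- function(raw, mu) {
  use <- which(raw > 1e-7 & mu > 0)
  fallback <- list(a0 = max(stats::median(raw[raw > 0], na.rm = TRUE), 1e-8),
                   a1 = 0)
  if (is.na(fallback$a0)) fallback$a0 <- 1e-8
  if (length(use) < 10) return(fallback)
  d <- raw[use]
  x <- 1 / mu[use]
  for (iter in 1:3) {
    fit <- tryCatch(
      stats::glm(d ~ x, family = stats::Gamma(link = "identity"),
                 start = c(fallback$a0, 1)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) return(fallback)
    co <- stats::coef(fit)
    pred <- pmax(co[1] + co[2] * x, 1e-8)
    keep <- d / pred < 15 & d / pred > 1e-4
    if (all(keep) || sum(keep) < 10) break
    d <- d[keep]
    x <- x[keep]
  }
  if (is.null(fit)) return(fallback)
  co <- stats::coef(fit)
  list(a0 = max(co[1], 1e-8), a1 = max(co[2], 0))
}

#' Two-group NB Wald test
#'
#' For each unit, log2FC is the log2 ratio of group-2 to group-1 mean
#' normalized counts (no shrinkage; a pseudocount of 0.5 enters only when a
#' group mean is exactly zero). The standard error comes from the NB Fisher
#' information of the two group log-means, I_g = sum_j s_j mu_g / (1 +
#' alpha s_j mu_g); the two-sided p is from the normal reference for
#' log(FC)/SE. BH adjustment is applied across all tested units.
#'
#' @param counts integer matrix (units x samples). Units failing upstream
#'   expression filters should be removed before calling.
#' @param group1Cols,group2Cols column indices or names of the two groups
#'   (disjoint).
#' @param sizeFactors size factors for all used columns (computed from
#'   \code{counts} if NULL).
#' @param dispersions per-unit dispersions (estimated if NULL).
#' @param shrinkDispersion passed to \code{\link{computeDispersions}}.
#' @return \link[S4Vectors]{DataFrame}: baseMean, log2FoldChange, lfcSE,
#'   stat, pvalue, padj.
#' @examples
#' m <- matrix(rnbinom(600, mu = 100, size = 20), 100, 6)
#' rownames(m) <- paste0("g", 1:100)
#' res <- nbWaldTest(m, 1:3, 4:6)
#' head(res)
#' @export
nbWaldTest <- function(counts, group1Cols, group2Cols, sizeFactors = NULL,
                       dispersions = NULL, shrinkDispersion = TRUE) {
  g1 <- if (is.character(group1Cols)) match(group1Cols, colnames(counts))
        else group1Cols
  g2 <- if (is.character(group2Cols)) match(group2Cols, colnames(counts))
        else group2Cols
  if (anyNA(g1) || anyNA(g2)) stopf("contrast names unknown samples")
  if (length(g1) == 0 || length(g2) == 0)
    stopf("contrast error: empty group")
  if (length(intersect(g1, g2))) stopf("contrast groups must be disjoint")
  sub <- counts[, c(g1, g2), drop = FALSE]
  grp <- rep(c("g1", "g2"), c(length(g1), length(g2)))
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(sub)
  if (length(sizeFactors) != ncol(sub))
    stopf("need one size factor per used sample")
  if (is.null(dispersions))
    dispersions <- computeDispersions(sub, grp, sizeFactors,
                                      shrink = shrinkDispersion)
  q <- sweep(sub, 2, sizeFactors, "/")
  s1 <- sizeFactors[grp == "g1"]
  s2 <- sizeFactors[grp == "g2"]
  m1 <- rowMeans(q[, grp == "g1", drop = FALSE])
  m2 <- rowMeans(q[, grp == "g2", drop = FALSE])
  baseMean <- rowMeans(q)

  # pseudocount only where a group mean is exactly zero
  m1t <- ifelse(m1 == 0, 0.5, m1)
  m2t <- ifelse(m2 == 0, 0.5, m2)
  beta <- log(m2t / m1t)
  info <- function(m, s) {
    mus <- outer(m, s)
    rowSums(mus / (1 + dispersions * mus))
  }
  varBeta <- 1 / info(m1t, s1) + 1 / info(m2t, s2)
  stat <- unname(beta / sqrt(varBeta))
  pvalue <- 2 * stats::pnorm(-abs(stat))
  res <- DataFrame(baseMean = unname(baseMean),
                   log2FoldChange = unname(beta) / log(2),
                   lfcSE = unname(sqrt(varBeta)) / log(2),
                   stat = stat, pvalue = pvalue,
                   padj = bhAdjust(pvalue),
                   row.names = rownames(counts))
  metadata(res) <- list(dispersions = dispersions,
                        sizeFactors = sizeFactors)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: padj_i = min over j with p_j >= p_i of
#' min(1, m p_j / rank_j). Input is validated, then delegated to
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, order-preserving.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed units
#'
#' DEG iff padj < alpha (strict); direction is the sign of log2FC (up =
#' higher in group 2). No additional fold-change threshold is applied.
#'
#' @param res DataFrame from \code{\link{nbWaldTest}}.
#' @param alpha significance level, default 0.05.
#' @return data.frame: unit, log2FoldChange, padj, direction ("up"/"down")
#'   for DEGs only.
#' @export
callDEGs <- function(res, alpha = 0.05) {
  sig <- which(res$padj < alpha)
  data.frame(unit = rownames(res)[sig],
             log2FoldChange = res$log2FoldChange[sig],
             padj = res$padj[sig],
             direction = ifelse(res$log2FoldChange[sig] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Run a genotype contrast within one condition
#'
#' Convenience wrapper: selects the two genotypes' samples under one
#' condition and runs \code{\link{nbWaldTest}} (group 1 = \code{genotype1},
#' so positive log2FC means higher in \code{genotype2}).
#'
#' @param hex a \linkS4class{HomoeoExperiment}.
#' @param genotype1,genotype2 genotype labels present in the design.
#' @param condition condition label.
#' @param genes optional gene subset (e.g. the post-filter expressed set).
#' @param sizeFactors optional size factors for the full experiment
#'   (subset internally); computed per contrast if NULL.
#' @return DataFrame as from \code{\link{nbWaldTest}}.
#' @export
runContrast <- function(hex, genotype1, genotype2, condition,
                        genes = NULL, sizeFactors = NULL) {
  d <- designInfo(hex)
  c1 <- d$sample[d$genotype == genotype1 & d$condition == condition]
  c2 <- d$sample[d$genotype == genotype2 & d$condition == condition]
  if (!length(c1) || !length(c2))
    stopf("contrast error: no samples for %s/%s under %s", genotype1,
          genotype2, condition)
  m <- SummarizedExperiment::assay(hex, "counts")
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  sf <- if (!is.null(sizeFactors)) sizeFactors[c(c1, c2)] else NULL
  nbWaldTest(m[, c(c1, c2), drop = FALSE], seq_along(c1),
             length(c1) + seq_along(c2), sizeFactors = sf)
}
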