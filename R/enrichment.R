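# One-tailed hypergeometric GO over-representation. The universe is the
# post-filter expressed gene set of the relevant subgenome; terms with
# fewer than minTermSize expressed genes are excluded before testing;
# BH correction runs across the surviving terms.

#' Hypergeometric over-representation of annotation terms
#'
#' For each term with at least \code{minTermSize} expressed genes, computes
#' the exact upper-tail hypergeometric probability P(X >= k) of drawing k
#' or more term genes when n DEGs are sampled from a universe of N genes of
#' which K carry the term, then BH-adjusts across terms.
#'
#' @param degSet character vector of DEG ids; must be a subset of
#'   \code{universe}.
#' @param universe character vector of expressed gene ids.
#' @param goMap data.frame (gene_id, term_id); genes without annotations
#'   simply carry no terms.
#' @param minTermSize terms with fewer expressed genes are dropped
#'   (default 5).
#' @param alpha significance level for the \code{significant} flag
#'   (default 0.05).
#' @return data.frame ordered by (padj, term): term, K (expressed genes
#'   with term), N (universe size), n (DEG-set size), k (overlap), pvalue,
#'   padj, significant.
#' @examples
#' std <- simulateHomoeoStudy(simConfig(nPairs = 60, seed = 3))
#' uni <- names(std$catalog)
#' enrichTerms(uni[1:20], uni, std$goMap)
#' @export
enrichTerms <- function(degSet, universe, goMap, minTermSize = 5,
                        alpha = 0.05) {
  if (anyDuplicated(universe)) stopf("universe contains duplicate ids")
  extra <- setdiff(degSet, universe)
  if (length(extra))
    stopf("DEG %s is not in the universe", extra[1])
  N <- length(universe)
  n <- length(degSet)
  map <- goMap[goMap$gene_id %in% universe, , drop = FALSE]
  termGenes <- split(map$gene_id, map$term_id)
  K <- lengths(termGenes)
  keep <- K >= minTermSize
  termGenes <- termGenes[keep]
  K <- K[keep]
  if (!length(K))
    return(data.frame(term = character(), K = integer(), N = integer(),
                      n = integer(), k = integer(), pvalue = numeric(),
                      padj = numeric(), significant = logical()))
  k <- vapply(termGenes, function(g) sum(g %in% degSet), integer(1))
  pvalue <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term = names(termGenes), K = as.integer(K), N = N,
                    n = n, k = as.integer(k), pvalue = pvalue,
                    padj = bhAdjust(pvalue), stringsAsFactors = FALSE)
  res$significant <- res$padj < alpha
  res <- res[order(res$padj, res$term), ]
  rownames(res) <- NULL
  res
}
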