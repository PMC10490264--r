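# Nine-mode classification of homoeologous pair expression. The A-vs-D
# call in the parents (Mix samples) is crossed with the A-vs-D call in the
# tetraploid progeny under the same condition:
#
#   mode 1 (A>D, A>D), 2 (A<D, A<D), 3 (A=D, A=D)   conserved regulation
#   mode 4 (A>D, A=D), 5 (A<D, A=D)                  convergent regulation
#   mode 6 (A=D, A>D), 7 (A=D, A<D)                  divergent regulation
#   mode 8 (A>D, A<D), 9 (A<D, A>D)                  reversed regulation

.RATIO_STATES <- c("A>D", "A<D", "A=D")
.REGULATION <- c("conserved", "conserved", "conserved", "convergent",
                 "convergent", "divergent", "divergent", "reversed",
                 "reversed")

#' Classify a pair of ratio calls into a mode and regulation type
#'
#' Total function on the 3 x 3 domain of parental and progeny A-vs-D calls.
#'
#' @param parentCall,progenyCall character vectors over
#'   \{"A>D", "A<D", "A=D"\}.
#' @return data.frame with integer \code{mode} (1-9) and character
#'   \code{regulation}.
#' @examples
#' classifyMode("A>D", "A<D")  # mode 8, reversed
#' @export
classifyMode <- function(parentCall, progenyCall) {
  bad <- !(parentCall %in% .RATIO_STATES) | !(progenyCall %in% .RATIO_STATES)
  if (any(bad))
    stopf("invalid ratio call '%s'",
          paste(parentCall[bad][1], progenyCall[bad][1]))
  mode <- match(paste(parentCall, progenyCall),
                paste(.MODE_PARENT, .MODE_PROGENY))
  data.frame(mode = mode, regulation = .REGULATION[mode],
             stringsAsFactors = FALSE)
}

#' A-copy vs D-copy contrast within one sample group
#'
#' Treats the two copies' counts across the same samples as the two groups
#' of a \code{\link{nbWaldTest}}: for each analyzed pair, group 1 holds the
#' D-copy counts and group 2 the A-copy counts of the selected samples, so
#' positive log2FC means A above D. Each sample's size factor is used for
#' both of its copy columns; the 10 percent length filter justifies not
#' length-normalizing.
#'
#' @param hex a \linkS4class{HomoeoExperiment}.
#' @param pairs \linkS4class{HomoeologPairs}; only pairs with an
#'   \code{analyzed} flag set to TRUE are tested if the column exists.
#' @param genotype,condition sample group selector (e.g. genotype "Mix"
#'   gives the parental contrast).
#' @param sizeFactors optional named size factors for the experiment's
#'   samples; computed from the full count matrix if NULL.
#' @return DataFrame as from \code{\link{nbWaldTest}}, rownames = pair ids,
#'   log2FoldChange = log2(A/D). BH adjustment is across the analyzed
#'   pairs of this contrast only.
#' @export
compareHomoeologs <- function(hex, pairs, genotype, condition,
                              sizeFactors = NULL) {
  pt <- pairs@pairs
  if ("analyzed" %in% colnames(pt)) pt <- pt[pt$analyzed, , drop = FALSE]
  if (nrow(pt) == 0) stopf("no analyzed pairs")
  d <- designInfo(hex)
  samples <- d$sample[d$genotype == genotype & d$condition == condition]
  if (!length(samples))
    stopf("no samples for genotype %s under %s", genotype, condition)
  m <- SummarizedExperiment::assay(hex, "counts")
  if (is.null(sizeFactors))
    sizeFactors <- computeSizeFactors(m[, samples, drop = FALSE])
  mat <- cbind(m[pt$dGene, samples, drop = FALSE],
               m[pt$aGene, samples, drop = FALSE])
  rownames(mat) <- pt$pairId
  colnames(mat) <- c(paste0(samples, ".D"), paste0(samples, ".A"))
  sf <- rep(unname(sizeFactors[samples]), 2)
  nbWaldTest(mat, seq_along(samples), length(samples) + seq_along(samples),
             sizeFactors = sf)
}

.ratioCall <- function(res, alpha = 0.05) {
  ifelse(res$padj < alpha,
         ifelse(res$log2FoldChange > 0, "A>D", "A<D"), "A=D")
}

#' Call expression modes for all analyzed pairs
#'
#' Combines the parental (Mix) and progeny A-vs-D contrasts of the same
#' condition into one mode call per pair.
#'
#' @param pairs \linkS4class{HomoeologPairs} (analyzed set).
#' @param deParent,deProgeny DataFrames from
#'   \code{\link{compareHomoeologs}}, rownames = pair ids.
#' @param alpha significance level for the ratio calls, default 0.05.
#' @return data.frame: pairId, parentCall, progenyCall, mode, regulation.
#' @export
callModes <- function(pairs, deParent, deProgeny, alpha = 0.05) {
  pt <- pairs@pairs
  if ("analyzed" %in% colnames(pt)) pt <- pt[pt$analyzed, , drop = FALSE]
  ids <- pt$pairId
  missP <- setdiff(ids, rownames(deParent))
  missG <- setdiff(ids, rownames(deProgeny))
  if (length(missP) || length(missG))
    stopf("pair %s missing from the %s contrast",
          c(missP, missG)[1], if (length(missP)) "parental" else "progeny")
  pc <- .ratioCall(deParent[ids, ], alpha)
  gc <- .ratioCall(deProgeny[ids, ], alpha)
  cl <- classifyMode(pc, gc)
  data.frame(pairId = ids, parentCall = pc, progenyCall = gc,
             mode = cl$mode, regulation = cl$regulation,
             stringsAsFactors = FALSE)
}

#' Summarize mode counts into percentages and regulation subtotals
#'
#' @param counts integer vector of length 9 (counts per mode).
#' @return list: \code{modes} (mode, regulation, count, pct),
#'   \code{regulation} (regulation, count, pct) and \code{total}.
#'   Percentages are 100 x count / total, rounded half-up to 2 decimals.
#' @examples
#' summarizeModeCounts(c(360, 357, 2645, 425, 279, 136, 204, 11, 3))
#' @export
summarizeModeCounts <- function(counts) {
  if (length(counts) != 9 || any(counts < 0))
    stopf("need 9 non-negative mode counts")
  total <- sum(counts)
  pct <- function(x) if (total == 0) rep(0, length(x))
                     else roundHalfUp(100 * x / total, 2)
  modes <- data.frame(mode = 1:9, regulation = .REGULATION,
                      count = as.integer(counts), pct = pct(counts),
                      stringsAsFactors = FALSE)
  reg <- stats::aggregate(count ~ regulation, modes, sum)
  reg <- reg[match(unique(.REGULATION), reg$regulation), ]
  reg$pct <- pct(reg$count)
  rownames(reg) <- NULL
  list(modes = modes, regulation = reg, total = total)
}

#' Summarize mode calls per line and condition
#'
#' @param modeCalls data.frame from \code{\link{callModes}}, optionally
#'   with \code{line} and \code{condition} columns (added by the pipeline);
#'   absent grouping columns yield a single group "all".
#' @return data.frame: line, condition, mode, regulation, count, pct.
#'   Counts partition the analyzed pairs of each group; percentages sum to
#'   100 up to rounding.
#' @export
summarizeModes <- function(modeCalls) {
  if (!"line" %in% colnames(modeCalls))
    modeCalls$line <- rep("all", nrow(modeCalls))
  if (!"condition" %in% colnames(modeCalls))
    modeCalls$condition <- rep("all", nrow(modeCalls))
  groups <- unique(modeCalls[, c("line", "condition"), drop = FALSE])
  out <- vector("list", nrow(groups))
  for (i in seq_len(max(nrow(groups), 0))) {
    sel <- modeCalls$line == groups$line[i] &
      modeCalls$condition == groups$condition[i]
    cnt <- tabulate(modeCalls$mode[sel], nbins = 9)
    s <- summarizeModeCounts(cnt)
    out[[i]] <- cbind(line = groups$line[i],
                      condition = groups$condition[i], s$modes,
                      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(line = character(), condition = character(),
                      mode = integer(), regulation = character(),
                      count = integer(), pct = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Attribute mode membership to per-copy expression changes
#'
#' Labels each pair with the direction of its A-copy and D-copy change in
#' the progeny relative to Mix (up / down / unchanged at padj < alpha) and
#' cross-tabulates the labels per mode.
#'
#' @param modeCalls data.frame from \code{\link{callModes}}.
#' @param deCopyA,deCopyD DataFrames from per-copy Mix-vs-progeny
#'   contrasts (\code{\link{runContrast}} on the pair genes), rownames =
#'   gene ids; \code{aGenes}, \code{dGenes} map pair ids to gene ids.
#' @param aGenes,dGenes character vectors (named by pairId or parallel to
#'   modeCalls rows) of the pairs' copy gene ids.
#' @param alpha significance level, default 0.05.
#' @return list: \code{labels} (pairId, mode, aChange, dChange) and
#'   \code{crossTab} (mode x "aChange/dChange" contingency counts).
#' @export
attributeModeChanges <- function(modeCalls, deCopyA, deCopyD, aGenes,
                                 dGenes, alpha = 0.05) {
  lab <- function(res, genes) {
    r <- res[genes, ]
    ifelse(r$padj < alpha,
           ifelse(r$log2FoldChange > 0, "up", "down"), "unchanged")
  }
  labels <- data.frame(pairId = modeCalls$pairId, mode = modeCalls$mode,
                       aChange = lab(deCopyA, aGenes),
                       dChange = lab(deCopyD, dGenes),
                       stringsAsFactors = FALSE)
  ct <- table(mode = factor(labels$mode, levels = 1:9),
              change = paste(labels$aChange, labels$dChange, sep = "/"))
  list(labels = labels, crossTab = ct)
}
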