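# Gene- and pair-level exclusion rules applied before any statistics.
# Order used by the pipeline: (1) HE-region / unplaced-scaffold exclusion,
# (2) mean-count window, then for pairs (3) transcript-length disparity and
# (4) expressed-in-at-least-one-subgenome. HE exclusion and the mean-count
# window act on disjoint evidence (position vs counts), so they commute.

#' Exclude genes in HE regions or on unplaced scaffolds
#'
#' A gene is removed iff its interval overlaps any HE interval by at least
#' one bp, or its chromosome is "unplaced". The exclusion is applied
#' identically to every genotype's analyses so that DEG universes stay
#' comparable between the euploid and the HE line.
#'
#' @param catalog GRanges gene catalog (names = gene ids).
#' @param heIntervals GRanges of HE regions (may be empty).
#' @return list: \code{kept} (character gene ids), \code{removed},
#'   \code{report} (data.frame rule/removed tallies).
#' @examples
#' std <- simulateHomoeoStudy(simConfig(nPairs = 40, seed = 1))
#' excludeHEGenes(std$catalog, std$heRegions)$report
#' @export
excludeHEGenes <- function(catalog, heIntervals) {
  known <- c(as.character(unique(seqnames(catalog))), .UNPLACED)
  bad <- setdiff(as.character(unique(seqnames(heIntervals))), known)
  if (length(bad))
    stopf("HE interval on unknown chromosome '%s'", bad[1])
  inHE <- rep(FALSE, length(catalog))
  if (length(heIntervals)) {
    hits <- findOverlaps(catalog, heIntervals, minoverlap = 1L)
    inHE[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  unplaced <- as.character(seqnames(catalog)) == .UNPLACED
  inHE[unplaced] <- FALSE  # tally each gene under one rule
  drop <- inHE | unplaced
  report <- data.frame(
    rule = c("he_region", "unplaced_scaffold"),
    removed = c(sum(inHE), sum(unplaced)),
    stringsAsFactors = FALSE)
  list(kept = names(catalog)[!drop], removed = names(catalog)[drop],
       report = report)
}

#' Mean-count expression window
#'
#' A gene survives iff its arithmetic mean raw count over all samples lies
#' in \code{[low, high]} (boundaries inclusive: "below 10 or above 5000"
#' removed).
#'
#' @param counts integer matrix (genes x samples).
#' @param low,high window bounds, defaults 10 and 5000.
#' @return character vector of surviving gene ids.
#' @export
filterByMeanCount <- function(counts, low = 10, high = 5000) {
  if (nrow(counts) == 0 || ncol(counts) == 0)
    stopf("empty count matrix")
  m <- rowMeans(counts)
  rownames(counts)[m >= low & m <= high]
}

#' Transcript-length disparity filter for homoeolog pairs
#'
#' A pair survives iff |len_A - len_D| / max(len_A, len_D) <= maxDisparity.
#' The longer transcript as denominator is this package's documented choice
#' (the conservative reading: it removes more pairs than the shorter-length
#' denominator would).
#'
#' @param pairs \linkS4class{HomoeologPairs}.
#' @param catalog GRanges carrying \code{transcript_length} for both copies.
#' @param maxDisparity default 0.10.
#' @return the pairs object with a logical \code{lengthOK} column added.
#' @export
filterPairsByLength <- function(pairs, catalog, maxDisparity = 0.10) {
  pt <- pairs@pairs
  lens <- mcols(catalog)$transcript_length
  names(lens) <- names(catalog)
  lA <- lens[pt$aGene]
  lD <- lens[pt$dGene]
  if (anyNA(lA) || anyNA(lD))
    stopf("missing transcript length for pair %s",
          pt$pairId[which(is.na(lA) | is.na(lD))[1]])
  disp <- abs(lA - lD) / pmax(lA, lD)
  pairs@pairs$lengthOK <- unname(disp <= maxDisparity)
  pairs
}

#' Expressed-in-at-least-one-subgenome filter
#'
#' A pair survives iff at least one copy passes the gene-level expression
#' criterion (mean raw count over all samples >= minMean; the same
#' threshold as the lower mean-count bound).
#'
#' @param pairs \linkS4class{HomoeologPairs}.
#' @param counts integer matrix over all samples.
#' @param minMean default 10.
#' @return the pairs object with a logical \code{expressed} column added.
#' @export
filterPairsByExpression <- function(pairs, counts, minMean = 10) {
  pt <- pairs@pairs
  m <- rowMeans(counts)
  mA <- ifelse(pt$aGene %in% rownames(counts), m[pt$aGene], 0)
  mD <- ifelse(pt$dGene %in% rownames(counts), m[pt$dGene], 0)
  pairs@pairs$expressed <- unname(mA >= minMean | mD >= minMean)
  pairs
}

#' Apply all pair-level filters and mark the analyzed set
#'
#' Pairs are analyzed iff both copies survive the HE/scaffold exclusion,
#' the length disparity is within bounds, and at least one copy is
#' expressed.
#'
#' @param pairs \linkS4class{HomoeologPairs}.
#' @param catalog GRanges gene catalog.
#' @param heIntervals GRanges of HE regions.
#' @param counts integer count matrix (all samples).
#' @param maxDisparity,minMean thresholds.
#' @return pairs with columns \code{heOK}, \code{lengthOK},
#'   \code{expressed}, \code{analyzed}.
#' @export
filterPairs <- function(pairs, catalog, heIntervals, counts,
                        maxDisparity = 0.10, minMean = 10) {
  keep <- excludeHEGenes(catalog, heIntervals)$kept
  pairs@pairs$heOK <- unname(pairs@pairs$aGene %in% keep &
                               pairs@pairs$dGene %in% keep)
  pairs <- filterPairsByLength(pairs, catalog, maxDisparity)
  pairs <- filterPairsByExpression(pairs, counts, minMean)
  pairs@pairs$analyzed <- pairs@pairs$heOK & pairs@pairs$lengthOK &
    pairs@pairs$expressed
  pairs
}

#' Gene-level filter report
#'
#' Applies the HE/scaffold exclusion then the mean-count window and tallies
#' removals per rule; removed + surviving partition the input at each step.
#'
#' @param catalog GRanges gene catalog.
#' @param heIntervals GRanges of HE regions.
#' @param counts integer count matrix.
#' @param low,high mean-count window.
#' @return list: \code{expressed} (surviving gene ids) and \code{report}
#'   (data.frame rule, removed, surviving).
#' @export
filterGenes <- function(catalog, heIntervals, counts, low = 10,
                        high = 5000) {
  he <- excludeHEGenes(catalog, heIntervals)
  n0 <- length(catalog)
  n1 <- length(he$kept)
  sub <- counts[intersect(rownames(counts), he$kept), , drop = FALSE]
  m <- rowMeans(sub)
  lowN <- sum(m < low)
  highN <- sum(m > high)
  expressed <- rownames(sub)[m >= low & m <= high]
  report <- data.frame(
    rule = c("he_region", "unplaced_scaffold", "mean_count_low",
             "mean_count_high"),
    removed = c(he$report$removed, lowN, highN),
    surviving = c(NA, n1, NA, length(expressed)),
    stringsAsFactors = FALSE)
  stopifnot(n0 - sum(he$report$removed) == n1,
            n1 - lowN - highN == length(expressed))
  list(expressed = expressed, report = report)
}
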