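# Per-subgenome DEG summaries and chromosomal distribution tracks.
# "Up-regulated" means higher in the tetraploid line than in the parental
# Mix; proportion denominators are the post-filter expressed-gene universe
# of each subgenome.

#' Summarize DEGs per subgenome and direction
#'
#' @param degs data.frame from \code{\link{callDEGs}} (columns unit,
#'   direction).
#' @param catalog GRanges gene catalog with \code{subgenome} mcols.
#' @param expressedSets named list ("A", "D") of post-filter expressed
#'   gene ids, the proportion denominators.
#' @return data.frame: subgenome, up, down, total, expressed,
#'   propUp, propDown, propTotal (proportions in [0, 1]).
#' @export
summarizeDEGs <- function(degs, catalog, expressedSets) {
  miss <- setdiff(degs$unit, names(catalog))
  if (length(miss))
    stopf("DEG %s not in the catalog", miss[1])
  sg <- mcols(catalog)$subgenome
  names(sg) <- names(catalog)
  out <- lapply(.SUBGENOMES, function(s) {
    universe <- expressedSets[[s]]
    sel <- degs[sg[degs$unit] == s, , drop = FALSE]
    up <- sum(sel$direction == "up")
    down <- sum(sel$direction == "down")
    n <- length(universe)
    data.frame(subgenome = s, up = up, down = down, total = up + down,
               expressed = n,
               propUp = if (n) up / n else 0,
               propDown = if (n) down / n else 0,
               propTotal = if (n) (up + down) / n else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chromosomal distribution tracks of DEGs
#'
#' @param degs data.frame from \code{\link{callDEGs}} with a
#'   \code{log2FoldChange} column.
#' @param catalog GRanges gene catalog (placed genes; unplaced DEGs are
#'   excluded upstream and rejected here).
#' @return list: \code{tracks} (chrom, position, gene, log2FoldChange,
#'   direction; ordered by chromosome then position) and \code{perChrom}
#'   (chrom, up, down, total).
#' @export
chromosomeTracks <- function(degs, catalog) {
  if (nrow(degs) == 0)
    return(list(tracks = data.frame(chrom = character(),
                                    position = integer(),
                                    gene = character(),
                                    log2FoldChange = numeric(),
                                    direction = character()),
                perChrom = data.frame(chrom = character(), up = integer(),
                                      down = integer(), total = integer())))
  gr <- catalog[degs$unit]
  chrom <- as.character(seqnames(gr))
  if (any(chrom == .UNPLACED))
    stopf("unplaced gene %s in DEG set; exclude scaffolds first",
          degs$unit[which(chrom == .UNPLACED)[1]])
  tracks <- data.frame(chrom = chrom, position = start(gr),
                       gene = degs$unit,
                       log2FoldChange = degs$log2FoldChange,
                       direction = degs$direction,
                       stringsAsFactors = FALSE)
  tracks <- tracks[order(tracks$chrom, tracks$position), ]
  rownames(tracks) <- NULL
  agg <- function(dir) {
    t <- table(tracks$chrom[tracks$direction == dir])
    as.integer(t[match(sort(unique(tracks$chrom)), names(t))])
  }
  chroms <- sort(unique(tracks$chrom))
  up <- agg("up")
  down <- agg("down")
  up[is.na(up)] <- 0L
  down[is.na(down)] <- 0L
  perChrom <- data.frame(chrom = chroms, up = up, down = down,
                         total = up + down, stringsAsFactors = FALSE)
  list(tracks = tracks, perChrom = perChrom)
}
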