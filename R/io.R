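# Tabular exchange formats: headered TSV throughout, BED-like interval
# tables in 0-based half-open coordinates on disk (converted to the 1-based
# closed GRanges convention in memory). Readers reject malformed input with
# row-addressed messages rather than coercing.

.readTSV <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.requireCols <- function(df, cols, path) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
}

#' Read / write a count matrix
#'
#' \code{counts.tsv} carries a \code{gene_id} column plus one integer column
#' per sample. Negative, missing or non-integer cells are rejected with the
#' offending row named.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
readCounts <- function(path) {
  df <- .readTSV(path)
  .requireCols(df, "gene_id", path)
  if (ncol(df) < 2) stopf("%s: no sample columns", path)
  dup <- which(duplicated(df$gene_id))
  if (length(dup))
    stopf("%s: duplicate gene id '%s' at row %d", path,
          df$gene_id[dup[1]], dup[1])
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(
    matrix(as.numeric(raw), nrow(raw), ncol(raw), dimnames = dimnames(raw)))
  badRow <- function(test, what) {
    i <- which(rowSums(test, na.rm = TRUE) > 0)
    if (length(i))
      stopf("%s: %s count at row %d (gene %s)", path, what, i[1],
            df$gene_id[i[1]])
  }
  badRow(is.na(raw) | raw == "NA", "missing")
  badRow(is.na(num), "non-numeric")
  badRow(num < 0, "negative")
  badRow(num != round(num), "non-integer")
  m <- num
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' @rdname readCounts
#' @param counts integer matrix (genes x samples).
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' Read / write a sample design sheet
#'
#' Columns: sample, genotype, condition, replicate. Vocabulary and key
#' uniqueness are enforced by \code{\link{validateDesign}}.
#' @param path file path.
#' @param genotypes,conditions allowed vocabularies.
#' @return data.frame.
#' @export
readDesign <- function(path, genotypes = .GENOTYPES,
                       conditions = .CONDITIONS) {
  df <- .readTSV(path)
  .requireCols(df, c("sample", "genotype", "condition", "replicate"), path)
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$replicate)) stopf("%s: non-integer replicate index", path)
  validateDesign(df, genotypes, conditions)
}

#' @rdname readDesign
#' @param design design data.frame.
#' @export
writeDesign <- function(design, path)
  .writeTSV(design[, c("sample", "genotype", "condition", "replicate")], path)

#' Read / write a gene catalog (BED-like, 0-based half-open on disk)
#'
#' Columns: chrom, start, end, gene_id, transcript_length. Unplaced scaffold
#' genes use chrom = "unplaced". On read, intervals become 1-based closed
#' GRanges; an interval written as (chrom, 800000, 51800000) therefore
#' contains position 800000 (0-based) and excludes 51800000.
#'
#' @param path file path.
#' @param subgenome "A" or "D", attached as a metadata column.
#' @return GRanges named by gene id with mcols subgenome and
#'   transcript_length.
#' @export
readGenes <- function(path, subgenome) {
  df <- .readTSV(path)
  .requireCols(df, c("chrom", "start", "end", "gene_id",
                     "transcript_length"), path)
  dup <- which(duplicated(df$gene_id))
  if (length(dup))
    stopf("%s: duplicate gene id '%s' at row %d", path,
          df$gene_id[dup[1]], dup[1])
  bad <- which(df$chrom != .UNPLACED & df$start >= df$end)
  if (length(bad))
    stopf("%s: start >= end at row %d (gene %s)", path, bad[1],
          df$gene_id[bad[1]])
  if (any(df$transcript_length <= 0))
    stopf("%s: non-positive transcript_length at row %d", path,
          which(df$transcript_length <= 0)[1])
  gr <- GRanges(df$chrom, IRanges(df$start + 1, pmax(df$end, df$start + 1)))
  names(gr) <- df$gene_id
  mcols(gr)$subgenome <- subgenome
  mcols(gr)$transcript_length <- as.integer(df$transcript_length)
  gr
}

#' @rdname readGenes
#' @param genes GRanges as returned by \code{readGenes}.
#' @export
writeGenes <- function(genes, path) {
  df <- data.frame(chrom = as.character(seqnames(genes)),
                   start = start(genes) - 1L, end = end(genes),
                   gene_id = names(genes),
                   transcript_length = mcols(genes)$transcript_length,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' Read / write the homoeolog pair table
#'
#' Columns: a_gene, d_gene, plus any logical filter-status columns.
#' @param path file path.
#' @return \linkS4class{HomoeologPairs}.
#' @export
readPairs <- function(path) {
  df <- .readTSV(path)
  .requireCols(df, c("a_gene", "d_gene"), path)
  dup <- which(duplicated(df$a_gene) | duplicated(df$d_gene))
  if (length(dup))
    stopf("%s: gene appears in more than one pair at row %d", path, dup[1])
  hp <- HomoeologPairs(df$a_gene, df$d_gene,
                       pairId = if ("pair_id" %in% colnames(df)) df$pair_id)
  for (f in setdiff(colnames(df), c("pair_id", "a_gene", "d_gene")))
    hp@pairs[[f]] <- as.logical(df[[f]])
  hp
}

#' @rdname readPairs
#' @param pairs \linkS4class{HomoeologPairs}.
#' @export
writePairs <- function(pairs, path) {
  df <- as.data.frame(pairs@pairs)
  colnames(df)[1:3] <- c("pair_id", "a_gene", "d_gene")
  .writeTSV(df, path)
}

#' Read / write HE region intervals (BED-like, 0-based half-open on disk)
#'
#' Columns: chrom, start, end, line, multiplier.
#' @param path file path.
#' @return GRanges with mcols line, multiplier.
#' @export
readIntervals <- function(path) {
  df <- .readTSV(path)
  .requireCols(df, c("chrom", "start", "end", "line", "multiplier"), path)
  if (any(df$start >= df$end))
    stopf("%s: empty interval at row %d", path,
          which(df$start >= df$end)[1])
  if (any(df$multiplier < 0))
    stopf("%s: negative multiplier at row %d", path,
          which(df$multiplier < 0)[1])
  gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
  mcols(gr)$line <- df$line
  mcols(gr)$multiplier <- as.numeric(df$multiplier)
  gr
}

#' @rdname readIntervals
#' @param intervals GRanges with mcols line, multiplier.
#' @export
writeIntervals <- function(intervals, path) {
  df <- data.frame(chrom = as.character(seqnames(intervals)),
                   start = start(intervals) - 1L, end = end(intervals),
                   line = mcols(intervals)$line,
                   multiplier = mcols(intervals)$multiplier,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' Read / write a GO annotation map
#'
#' Columns: gene_id, term_id; one row per annotation.
#' @param path file path.
#' @return data.frame (gene_id, term_id).
#' @export
readGOMap <- function(path) {
  df <- .readTSV(path)
  .requireCols(df, c("gene_id", "term_id"), path)
  dup <- which(duplicated(df[, c("gene_id", "term_id")]))
  if (length(dup))
    stopf("%s: duplicate annotation at row %d", path, dup[1])
  df[, c("gene_id", "term_id")]
}

#' @rdname readGOMap
#' @param goMap data.frame (gene_id, term_id).
#' @export
writeGOMap <- function(goMap, path)
  .writeTSV(goMap[, c("gene_id", "term_id")], path)

#' Write a simulated study to a directory
#'
#' Emits counts.tsv, design.tsv, genes_A.bed, genes_D.bed, pairs.tsv,
#' he_regions.bed, go_map.tsv and truth.tsv.
#'
#' @param study output of \code{\link{simulateHomoeoStudy}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hex <- study$experiment
  writeCounts(SummarizedExperiment::assay(hex, "counts"),
              file.path(dir, "counts.tsv"))
  writeDesign(designInfo(hex), file.path(dir, "design.tsv"))
  writeGenes(study$catalogA, file.path(dir, "genes_A.bed"))
  writeGenes(study$catalogD, file.path(dir, "genes_D.bed"))
  writePairs(study$pairs, file.path(dir, "pairs.tsv"))
  writeIntervals(study$heRegions, file.path(dir, "he_regions.bed"))
  writeGOMap(study$goMap, file.path(dir, "go_map.tsv"))
  .writeTSV(pairTruth(study$truth), file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a study back from a directory written by \code{\link{writeStudy}}
#'
#' @param dir directory containing the study files.
#' @return list with experiment, catalog, catalogA, catalogD, pairs,
#'   heRegions, goMap (truth.tsv, if present, under \code{truth} as a
#'   data.frame).
#' @export
readStudy <- function(dir) {
  counts <- readCounts(file.path(dir, "counts.tsv"))
  design <- readDesign(file.path(dir, "design.tsv"))
  catalogA <- readGenes(file.path(dir, "genes_A.bed"), "A")
  catalogD <- readGenes(file.path(dir, "genes_D.bed"), "D")
  catalog <- suppressWarnings(c(catalogA, catalogD))
  pairs <- readPairs(file.path(dir, "pairs.tsv"))
  heRegions <- readIntervals(file.path(dir, "he_regions.bed"))
  goMap <- readGOMap(file.path(dir, "go_map.tsv"))
  truthPath <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truthPath)) .readTSV(truthPath) else NULL
  hex <- HomoeoExperiment(counts, design, catalog)
  list(experiment = hex, catalog = catalog, catalogA = catalogA,
       catalogD = catalogD, pairs = pairs, heRegions = heRegions,
       goMap = goMap, truth = truth)
}
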