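#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end width
#' @importFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' HomoeoExperiment: counts, design and gene catalog in one container
#'
#' Extends \linkS4class{RangedSummarizedExperiment}: the \code{counts} assay
#' holds non-negative integer read counts (genes x samples), \code{rowRanges}
#' is the gene catalog (chromosome intervals with \code{subgenome} and
#' \code{transcript_length} metadata columns; unplaced scaffold genes sit on
#' the pseudo-chromosome \code{"unplaced"}), and \code{colData} binds each
#' sample to its genotype, condition and replicate.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}.
#' @export
setClass("HomoeoExperiment", contains = "RangedSummarizedExperiment")

.validHomoeoExperiment <- function(object) {
  msg <- NULL
  if (!("counts" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts contain missing values")
    else {
      if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(m != round(m))) msg <- c(msg, "counts must be integer-valued")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("genotype", "condition", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  else if (anyDuplicated(paste(cd$genotype, cd$condition, cd$replicate)))
    msg <- c(msg, "(genotype, condition, replicate) must be unique")
  rr <- SummarizedExperiment::rowRanges(object)
  rneed <- c("subgenome", "transcript_length")
  rmiss <- setdiff(rneed, colnames(mcols(rr)))
  if (length(rmiss))
    msg <- c(msg, paste0("rowRanges lack metadata column(s): ",
                         paste(rmiss, collapse = ", ")))
  else {
    if (!all(mcols(rr)$subgenome %in% .SUBGENOMES))
      msg <- c(msg, "subgenome must be 'A' or 'D'")
    if (any(mcols(rr)$transcript_length <= 0))
      msg <- c(msg, "transcript_length must be positive")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("HomoeoExperiment", .validHomoeoExperiment)

#' Construct a HomoeoExperiment
#'
#' @param counts integer matrix, genes x samples, rownames = gene ids,
#'   colnames = sample ids.
#' @param design data.frame with one row per sample and columns
#'   \code{sample}, \code{genotype}, \code{condition}, \code{replicate};
#'   row order may differ from column order of \code{counts} (matched by
#'   \code{sample}).
#' @param catalog \link[GenomicRanges]{GRanges} named by gene id with
#'   metadata columns \code{subgenome} and \code{transcript_length},
#'   covering every row of \code{counts}.
#' @return a \linkS4class{HomoeoExperiment}.
#' @examples
#' std <- simulateHomoeoStudy(simConfig(nPairs = 20, seed = 1))
#' std$experiment
#' @export
HomoeoExperiment <- function(counts, design, catalog) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene ids as rownames and sample ids as colnames")
  design <- validateDesign(design)
  if (!setequal(design$sample, colnames(counts)))
    stopf("design samples and count-matrix columns disagree")
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  missing <- setdiff(rownames(counts), names(catalog))
  if (length(missing))
    stopf("catalog lacks %d genes present in counts (first: %s)",
          length(missing), missing[1])
  rr <- catalog[rownames(counts)]
  cd <- DataFrame(genotype = design$genotype, condition = design$condition,
                  replicate = design$replicate, row.names = design$sample)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = rr, colData = cd)
  new("HomoeoExperiment", se)
}

#' Validate a sample design sheet
#'
#' Checks required columns, vocabulary membership and uniqueness of the
#' (genotype, condition, replicate) key.
#'
#' @param design data.frame with columns \code{sample}, \code{genotype},
#'   \code{condition}, \code{replicate}.
#' @param genotypes,conditions allowed vocabularies.
#' @return the design, with factors coerced to character.
#' @export
validateDesign <- function(design, genotypes = .GENOTYPES,
                           conditions = .CONDITIONS) {
  need <- c("sample", "genotype", "condition", "replicate")
  miss <- setdiff(need, colnames(design))
  if (length(miss))
    stopf("design lacks column(s): %s", paste(miss, collapse = ", "))
  design$sample <- as.character(design$sample)
  design$genotype <- as.character(design$genotype)
  design$condition <- as.character(design$condition)
  bad <- which(!design$genotype %in% genotypes)
  if (length(bad))
    stopf("design row %d: unknown genotype '%s'", bad[1],
          design$genotype[bad[1]])
  bad <- which(!design$condition %in% conditions)
  if (length(bad))
    stopf("design row %d: unknown condition '%s'", bad[1],
          design$condition[bad[1]])
  if (anyDuplicated(design$sample))
    stopf("duplicate sample id in design")
  key <- paste(design$genotype, design$condition, design$replicate)
  if (anyDuplicated(key))
    stopf("duplicate (genotype, condition, replicate) in design")
  design
}

#' @describeIn HomoeoExperiment the gene catalog (GRanges) of an experiment.
#' @param x a HomoeoExperiment.
#' @export
geneCatalog <- function(x) SummarizedExperiment::rowRanges(x)

#' @describeIn HomoeoExperiment sample design as a data.frame with a
#'   \code{sample} column.
#' @export
designInfo <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample = rownames(cd), genotype = cd$genotype,
             condition = cd$condition, replicate = cd$replicate,
             stringsAsFactors = FALSE)
}

#' @describeIn HomoeoExperiment per-gene subgenome labels ("A"/"D").
#' @export
subgenomes <- function(x) {
  sg <- mcols(SummarizedExperiment::rowRanges(x))$subgenome
  names(sg) <- rownames(x)
  sg
}

setMethod("show", "HomoeoExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("HomoeoExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  genotypes: ", paste(unique(cd$genotype), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(cd$condition), collapse = ", "), "\n")
  sg <- table(mcols(SummarizedExperiment::rowRanges(object))$subgenome)
  cat("  subgenomes:", paste(names(sg), sg, sep = "=", collapse = ", "), "\n")
})

#' HomoeologPairs: 1:1 collinear homoeologous gene pairs
#'
#' A table of A-copy/D-copy gene pairs. Each gene may appear in at most one
#' pair (the 1:1 collinearity contract). Filter steps annotate pairs with
#' logical status columns rather than dropping rows, so the provenance of
#' the analyzed set stays inspectable.
#'
#' @slot pairs DataFrame with character columns \code{aGene}, \code{dGene}
#'   and an id column \code{pairId}; further columns are filter flags.
#' @export
setClass("HomoeologPairs", representation(pairs = "DataFrame"))

.validHomoeologPairs <- function(object) {
  p <- object@pairs
  msg <- NULL
  need <- c("pairId", "aGene", "dGene")
  miss <- setdiff(need, colnames(p))
  if (length(miss))
    return(paste0("pairs lack column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(p$pairId)) msg <- c(msg, "pairId must be unique")
  if (anyDuplicated(p$aGene)) msg <- c(msg, "an A gene appears in >1 pair")
  if (anyDuplicated(p$dGene)) msg <- c(msg, "a D gene appears in >1 pair")
  if (is.null(msg)) TRUE else msg
}
setValidity("HomoeologPairs", .validHomoeologPairs)

#' Construct a HomoeologPairs table
#' @param aGene,dGene character vectors of equal length (gene ids).
#' @param pairId optional pair ids; generated if missing.
#' @return a \linkS4class{HomoeologPairs}.
#' @export
HomoeologPairs <- function(aGene, dGene, pairId = NULL) {
  if (length(aGene) != length(dGene))
    stopf("aGene and dGene must have equal length")
  if (is.null(pairId))
    pairId <- sprintf("P%05d", seq_along(aGene))
  new("HomoeologPairs", pairs = DataFrame(pairId = as.character(pairId),
                                          aGene = as.character(aGene),
                                          dGene = as.character(dGene)))
}

#' @describeIn HomoeologPairs number of pairs.
#' @param x a HomoeologPairs object.
#' @export
nPairs <- function(x) nrow(x@pairs)

#' @describeIn HomoeologPairs underlying table as a data.frame.
#' @export
pairTable <- function(x) as.data.frame(x@pairs)

setMethod("show", "HomoeologPairs", function(object) {
  cat("HomoeologPairs:", nrow(object@pairs), "pairs\n")
  flags <- setdiff(colnames(object@pairs), c("pairId", "aGene", "dGene"))
  if (length(flags))
    for (f in flags)
      cat("  ", f, ": ", sum(object@pairs[[f]]), " TRUE\n", sep = "")
})

#' subset pairs by a logical or index vector
#' @param x HomoeologPairs; @param i index.
#' @export
setMethod("[", "HomoeologPairs", function(x, i, ...) {
  initialize(x, pairs = x@pairs[i, , drop = FALSE])
})
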