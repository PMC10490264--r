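# End-to-end orchestration: simulate (or read) -> filter -> DE -> modes ->
# summaries -> enrichment. Every stage writes its outputs as TSV so any
# stage can be re-run in isolation; failures abort with stage-named errors
# before later outputs are written.

#' Assemble a pipeline configuration
#'
#' @param simulation a \linkS4class{SimulationConfig}, or NULL to read a
#'   previously written study from \code{inputDir}.
#' @param inputDir directory of study files (see \code{\link{readStudy}});
#'   ignored when \code{simulation} is given.
#' @param lines tetraploid lines to analyze against Mix.
#' @param conditions conditions to analyze.
#' @param alpha DEG / ratio-call significance level.
#' @param meanCountRange inclusive mean raw count window.
#' @param maxLengthDisparity pair transcript-length disparity bound.
#' @param minTermSize minimum expressed genes per GO term.
#' @return validated config list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(simulation = NULL, inputDir = NULL,
                           lines = c("EUP", "X190"),
                           conditions = .CONDITIONS, alpha = 0.05,
                           meanCountRange = c(10, 5000),
                           maxLengthDisparity = 0.10, minTermSize = 5) {
  if (is.null(simulation) && is.null(inputDir))
    stopf("either a simulation block or an input directory is required")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (any(meanCountRange <= 0) || diff(meanCountRange) < 0)
    stopf("meanCountRange must be positive and increasing")
  if (maxLengthDisparity <= 0) stopf("maxLengthDisparity must be positive")
  if (minTermSize < 1) stopf("minTermSize must be >= 1")
  structure(list(simulation = simulation, inputDir = inputDir,
                 lines = lines, conditions = conditions, alpha = alpha,
                 meanCountRange = meanCountRange,
                 maxLengthDisparity = maxLengthDisparity,
                 minTermSize = minTermSize),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full homoeolog-expression pipeline
#'
#' Stages: input (simulate or read), gene and pair filtering, tetraploid
#' vs Mix differential expression per line and condition, per-subgenome
#' DEG summaries with chromosome tracks, nine-mode classification with
#' per-copy change attribution, and GO over-representation per subgenome.
#' Deterministic given the configuration (the simulation seed covers all
#' randomness).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory for the report bundle.
#' @return invisibly, a list with all in-memory results: study, filter,
#'   de (per line x condition), degSummary, tracks, modeCalls,
#'   modeSummary, attribution, enrichment.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(simulation = simConfig(nPairs = 80, seed = 11),
#'                       conditions = "mock-2d", lines = "EUP")
#' res <- runPipeline(cfg, tempfile("pipe"))
#' head(res$modeSummary)
#' }
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  study <- .stage("input", {
    if (!is.null(config$simulation)) simulateHomoeoStudy(config$simulation)
    else readStudy(config$inputDir)
  })
  hex <- study$experiment
  counts <- SummarizedExperiment::assay(hex, "counts")
  catalog <- geneCatalog(hex)

  filt <- .stage("filter", {
    fg <- filterGenes(catalog, study$heRegions, counts,
                      low = config$meanCountRange[1],
                      high = config$meanCountRange[2])
    sg <- subgenomes(hex)
    expressedSets <- split(fg$expressed, sg[fg$expressed])
    pairs <- filterPairs(study$pairs, catalog, study$heRegions, counts,
                         maxDisparity = config$maxLengthDisparity,
                         minMean = config$meanCountRange[1])
    pairReport <- data.frame(
      rule = c("pair_he", "pair_length", "pair_expressed", "pair_analyzed"),
      removed = c(sum(!pairs@pairs$heOK), sum(!pairs@pairs$lengthOK),
                  sum(!pairs@pairs$expressed), NA),
      surviving = c(NA, NA, NA, sum(pairs@pairs$analyzed)),
      stringsAsFactors = FALSE)
    .writeTSV(rbind(fg$report, pairReport),
              file.path(outDir, "filter_report.tsv"))
    writePairs(pairs, file.path(outDir, "pairs_filtered.tsv"))
    list(expressed = fg$expressed, expressedSets = expressedSets,
         pairs = pairs, report = fg$report)
  })

  # size factors over the samples the contrasts use (Mix and the
  # tetraploid lines); pure-parent samples express only one subgenome, so
  # no gene has a nonzero geometric mean across them
  sizeFactors <- .stage("normalize", {
    d <- designInfo(hex)
    use <- d$sample[d$genotype %in% c("Mix", config$lines)]
    computeSizeFactors(counts[, use, drop = FALSE])
  })

  de <- list()
  degSummary <- list()
  trackSummary <- list()
  .stage("de", {
    for (line in config$lines) for (cond in config$conditions) {
      key <- paste(line, cond, sep = ".")
      res <- runContrast(hex, "Mix", line, cond, genes = filt$expressed,
                         sizeFactors = sizeFactors)
      de[[key]] <- res
      out <- data.frame(gene_id = rownames(res), as.data.frame(res))
      .writeTSV(out, file.path(outDir, sprintf("de_%s_%s.tsv", line, cond)))
    }
  })

  .stage("deg_summary", {
    for (key in names(de)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      degs <- callDEGs(de[[key]], config$alpha)
      s <- summarizeDEGs(degs, catalog, filt$expressedSets)
      degSummary[[key]] <- cbind(line = parts[1], condition = parts[2], s,
                                  stringsAsFactors = FALSE)
      tr <- chromosomeTracks(degs, catalog)
      trackSummary[[key]] <- cbind(line = parts[1], condition = parts[2],
                                    tr$perChrom, stringsAsFactors = FALSE)
    }
    .writeTSV(do.call(rbind, degSummary),
              file.path(outDir, "deg_summary.tsv"))
    .writeTSV(do.call(rbind, trackSummary), file.path(outDir, "tracks.tsv"))
  })

  modeCalls <- list()
  attribution <- list()
  .stage("modes", {
    analyzed <- filt$pairs[filt$pairs@pairs$analyzed]
    pt <- analyzed@pairs
    for (cond in config$conditions) {
      deParent <- compareHomoeologs(hex, analyzed, "Mix", cond,
                                    sizeFactors = sizeFactors)
      for (line in config$lines) {
        key <- paste(line, cond, sep = ".")
        deProg <- compareHomoeologs(hex, analyzed, line, cond,
                                    sizeFactors = sizeFactors)
        mc <- callModes(analyzed, deParent, deProg, config$alpha)
        mc$line <- line
        mc$condition <- cond
        modeCalls[[key]] <- mc
        deA <- runContrast(hex, "Mix", line, cond, genes = pt$aGene,
                           sizeFactors = sizeFactors)
        deD <- runContrast(hex, "Mix", line, cond, genes = pt$dGene,
                           sizeFactors = sizeFactors)
        att <- attributeModeChanges(mc, deA, deD, pt$aGene, pt$dGene,
                                    config$alpha)
        attribution[[key]] <- cbind(line = line, condition = cond,
                                     att$labels, stringsAsFactors = FALSE)
      }
    }
    allCalls <- do.call(rbind, modeCalls)
    .writeTSV(allCalls, file.path(outDir, "modes.tsv"))
    .writeTSV(summarizeModes(allCalls),
              file.path(outDir, "mode_summary.tsv"))
    .writeTSV(do.call(rbind, attribution),
              file.path(outDir, "attribution.tsv"))
  })

  enrichment <- list()
  .stage("enrichment", {
    for (key in names(de)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      degs <- callDEGs(de[[key]], config$alpha)
      sg <- subgenomes(hex)
      for (s in .SUBGENOMES) {
        uni <- filt$expressedSets[[s]]
        dset <- intersect(degs$unit, uni)
        er <- enrichTerms(dset, uni, study$goMap,
                          minTermSize = config$minTermSize,
                          alpha = config$alpha)
        if (nrow(er))
          enrichment[[paste(key, s, sep = ".")]] <-
            cbind(line = parts[1], condition = parts[2], subgenome = s,
                  er, stringsAsFactors = FALSE)
      }
    }
    if (length(enrichment))
      .writeTSV(do.call(rbind, enrichment),
                file.path(outDir, "enrichment.tsv"))
  })

  .stage("log", {
    cfgFile <- file.path(outDir, "config_used.txt")
    writeLines(utils::capture.output(utils::str(config)), cfgFile)
    log <- c(
      sprintf("HomoeoExpress %s",
              as.character(utils::packageVersion("HomoeoExpress"))),
      sprintf("seed: %s",
              if (!is.null(config$simulation)) config$simulation@seed
              else "none (external inputs)"),
      sprintf("config md5: %s", unname(tools::md5sum(cfgFile))),
      sprintf("genes: %d  expressed: %d", nrow(hex),
              length(filt$expressed)),
      sprintf("analyzed pairs: %d", sum(filt$pairs@pairs$analyzed)),
      sprintf("filter tallies: %s",
              paste(filt$report$rule, filt$report$removed, sep = "=",
                    collapse = ", ")))
    writeLines(log, file.path(outDir, "run_log.txt"))
  })

  invisible(list(study = study, filter = filt, sizeFactors = sizeFactors,
                 de = de, degSummary = do.call(rbind, degSummary),
                 tracks = do.call(rbind, trackSummary),
                 modeCalls = do.call(rbind, modeCalls),
                 modeSummary = summarizeModes(do.call(rbind, modeCalls)),
                 attribution = do.call(rbind, attribution),
                 enrichment = if (length(enrichment))
                   do.call(rbind, enrichment) else NULL))
}
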