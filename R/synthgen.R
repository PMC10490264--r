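#' SimulationConfig: parameters of the synthetic allopolyploid study
#'
#' Describes the simulated design: two diploid parents (A and D genomes), an
#' in-silico equal-mass parental mixture ("Mix"), a euploid allotetraploid
#' (EUP) and a homoeologous-exchange line (X190), each sampled under four
#' conditions. Defaults emulate a wheat-like layout: seven chromosomes per
#' subgenome, HE intervals on chromosomes 2 and 3 with duplicated (x2) and
#' deleted (x0) copies, negative binomial counts.
#'
#' @slot nPairs number of 1:1 collinear homoeologous pairs.
#' @slot nSingletonA,nSingletonD placed genes without a homoeologous partner.
#' @slot nScaffoldA,nScaffoldD genes on unplaced scaffolds.
#' @slot replicates replicates per (genotype, condition) group (>= 2).
#' @slot dispersion NB dispersion alpha (Var = mu + alpha mu^2); 0 = Poisson.
#' @slot libSizeRange multiplicative library-size factor range (log-uniform).
#' @slot foldChange linear fold magnitude planted for unequal states (> 1).
#' @slot baselineRange parent-scale baseline expression rate range
#'   (log-uniform; expected counts at library factor 1).
#' @slot lengthDisparityFraction fraction of pairs planted with transcript
#'   length disparity exceeding 10 percent.
#' @slot chromLengthA,chromLengthD chromosome lengths in bp.
#' @slot nChrom chromosomes per subgenome.
#' @slot heRegions data.frame (chrom, start, end, line, multiplier) in
#'   0-based half-open coordinates, as written to BED.
#' @slot modeProportions matrix (conditions x 9) of planted mode
#'   probabilities; rows sum to 1.
#' @slot changedCopyBias probability that a single-copy mode change is
#'   realized on the D copy rather than the A copy.
#' @slot conditions,genotypes study vocabulary.
#' @slot degFractionA,degFractionD fraction of singleton genes planted as
#'   progeny-vs-Mix DEGs, per subgenome.
#' @slot burstChrom,burstCondition,burstFraction chromosome-specific DEG
#'   burst (emulates a chromosome with a locally elevated DEG count).
#' @slot goTerms number of background GO terms.
#' @slot goBaseProbRange per-term annotation probability range.
#' @slot goEnrichedBaseProb baseline annotation probability of the planted
#'   enriched term.
#' @slot goEnrichedOR odds ratio by which changed genes are preferentially
#'   annotated with the enriched term.
#' @slot seed master seed; sub-streams are derived per stage.
#' @export
setClass("SimulationConfig", representation(
  nPairs = "numeric", nSingletonA = "numeric", nSingletonD = "numeric",
  nScaffoldA = "numeric", nScaffoldD = "numeric",
  replicates = "numeric", dispersion = "numeric",
  libSizeRange = "numeric", foldChange = "numeric",
  baselineRange = "numeric", lengthDisparityFraction = "numeric",
  chromLengthA = "numeric", chromLengthD = "numeric", nChrom = "numeric",
  heRegions = "data.frame", modeProportions = "matrix",
  changedCopyBias = "numeric",
  conditions = "character", genotypes = "character",
  degFractionA = "numeric", degFractionD = "numeric",
  burstChrom = "character", burstCondition = "character",
  burstFraction = "numeric",
  goTerms = "numeric", goBaseProbRange = "numeric",
  goEnrichedBaseProb = "numeric", goEnrichedOR = "numeric",
  seed = "numeric"))

.validSimulationConfig <- function(object) {
  msg <- NULL
  cnt <- c(nPairs = object@nPairs, nSingletonA = object@nSingletonA,
           nSingletonD = object@nSingletonD, nScaffoldA = object@nScaffoldA,
           nScaffoldD = object@nScaffoldD)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "gene counts must be non-negative integers")
  if (object@nPairs < 1) msg <- c(msg, "nPairs must be >= 1")
  if (object@replicates < 2) msg <- c(msg, "replicates must be >= 2")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (length(object@libSizeRange) != 2 || any(object@libSizeRange <= 0) ||
      diff(object@libSizeRange) < 0)
    msg <- c(msg, "libSizeRange must be two positive increasing values")
  if (object@foldChange <= 1) msg <- c(msg, "foldChange must be > 1")
  if (object@lengthDisparityFraction < 0 ||
      object@lengthDisparityFraction > 1)
    msg <- c(msg, "lengthDisparityFraction must be in [0, 1]")
  if (!all(rownames(object@modeProportions) == object@conditions))
    msg <- c(msg, "modeProportions rows must match conditions")
  if (ncol(object@modeProportions) != 9 ||
      any(object@modeProportions < 0) ||
      any(abs(rowSums(object@modeProportions) - 1) > 1e-8))
    msg <- c(msg, "modeProportions must be 9 non-negative columns summing to 1 per condition")
  he <- object@heRegions
  if (nrow(he)) {
    need <- c("chrom", "start", "end", "line", "multiplier")
    if (!all(need %in% colnames(he)))
      msg <- c(msg, "heRegions need columns chrom, start, end, line, multiplier")
    else if (any(he$multiplier < 0))
      msg <- c(msg, "HE copy-number multipliers must be non-negative")
  }
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "a seed is mandatory")
  # placeability: genes per chromosome must fit with room to spare
  perChrom <- ceiling((object@nPairs + max(object@nSingletonA,
                                           object@nSingletonD)) /
                        object@nChrom)
  if (perChrom * 2100 > min(object@chromLengthA, object@chromLengthD))
    msg <- c(msg, "more genes than placeable on the configured chromosomes")
  if (is.null(msg)) TRUE else msg
}
setValidity("SimulationConfig", .validSimulationConfig)

#' Default planted mode proportions (one row per condition)
#' @keywords internal
.defaultModeProportions <- function(conditions) {
  p <- c(0.08, 0.08, 0.60, 0.09, 0.07, 0.03, 0.045, 0.003, 0.002)
  m <- matrix(rep(p, length(conditions)), nrow = length(conditions),
              byrow = TRUE,
              dimnames = list(conditions, paste0("mode", 1:9)))
  m
}

#' Default homoeologous-exchange intervals (0-based half-open)
#'
#' Two homozygous HE events: the terminal segment of 2D replaced by 2A
#' (2A genes duplicated, 2D genes deleted) and the terminal segment of 3D
#' replaced by 3A.
#' @param chromLengthA,chromLengthD chromosome lengths in bp.
#' @return data.frame with columns chrom, start, end, line, multiplier.
#' @export
defaultHERegions <- function(chromLengthA = 750e6, chromLengthD = 650e6) {
  data.frame(
    chrom = c("Chr2A", "Chr2D", "Chr3A", "Chr3D"),
    start = c(8e5, 4e5, 684.6e6, 557.4e6),
    end = c(51.8e6, 58e6, chromLengthA, chromLengthD),
    line = "X190",
    multiplier = c(2, 0, 2, 0),
    stringsAsFactors = FALSE)
}

#' Build a SimulationConfig
#'
#' @param nPairs,nSingletonA,nSingletonD,nScaffoldA,nScaffoldD gene counts.
#' @param replicates replicates per sample group.
#' @param dispersion NB dispersion (0 gives Poisson counts).
#' @param libSizeRange library-size factor range.
#' @param foldChange planted linear fold for unequal states.
#' @param baselineRange baseline expression-rate range.
#' @param lengthDisparityFraction fraction of pairs violating the 10 percent
#'   transcript-length rule.
#' @param chromLengthA,chromLengthD,nChrom chromosome geometry.
#' @param heRegions HE interval table (see \code{\link{defaultHERegions}}).
#' @param modeProportions length-9 vector or (conditions x 9) matrix.
#' @param changedCopyBias probability a one-copy change hits the D copy.
#' @param conditions,genotypes study vocabulary.
#' @param degFractionA,degFractionD singleton DEG planting fractions.
#' @param burstChrom,burstCondition,burstFraction localized DEG burst.
#' @param goTerms,goBaseProbRange,goEnrichedBaseProb,goEnrichedOR GO map
#'   parameters.
#' @param seed master seed (mandatory).
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(nPairs = 100, seed = 7)
#' @export
simConfig <- function(nPairs = 2500,
                      nSingletonA = 600, nSingletonD = 600,
                      nScaffoldA = 60, nScaffoldD = 60,
                      replicates = 3, dispersion = 0.05,
                      libSizeRange = c(0.7, 1.4), foldChange = 4,
                      baselineRange = c(50, 1500),
                      lengthDisparityFraction = 0.2,
                      chromLengthA = 750e6, chromLengthD = 650e6,
                      nChrom = 7,
                      heRegions = defaultHERegions(chromLengthA, chromLengthD),
                      modeProportions = NULL,
                      changedCopyBias = 0.5,
                      conditions = .CONDITIONS, genotypes = .GENOTYPES,
                      degFractionA = 0.05, degFractionD = 0.10,
                      burstChrom = "Chr5D", burstCondition = "mock-2d",
                      burstFraction = 0.30,
                      goTerms = 40, goBaseProbRange = c(0.01, 0.06),
                      goEnrichedBaseProb = 0.05, goEnrichedOR = 20,
                      seed) {
  if (missing(seed)) stopf("a simulation seed is mandatory")
  if (is.null(modeProportions))
    modeProportions <- .defaultModeProportions(conditions)
  if (is.null(dim(modeProportions)))
    modeProportions <- matrix(rep(modeProportions, length(conditions)),
                              nrow = length(conditions), byrow = TRUE,
                              dimnames = list(conditions, paste0("mode", 1:9)))
  new("SimulationConfig", nPairs = nPairs, nSingletonA = nSingletonA,
      nSingletonD = nSingletonD, nScaffoldA = nScaffoldA,
      nScaffoldD = nScaffoldD, replicates = replicates,
      dispersion = dispersion, libSizeRange = libSizeRange,
      foldChange = foldChange, baselineRange = baselineRange,
      lengthDisparityFraction = lengthDisparityFraction,
      chromLengthA = chromLengthA, chromLengthD = chromLengthD,
      nChrom = nChrom, heRegions = heRegions,
      modeProportions = modeProportions, changedCopyBias = changedCopyBias,
      conditions = conditions, genotypes = genotypes,
      degFractionA = degFractionA, degFractionD = degFractionD,
      burstChrom = burstChrom, burstCondition = burstCondition,
      burstFraction = burstFraction, goTerms = goTerms,
      goBaseProbRange = goBaseProbRange,
      goEnrichedBaseProb = goEnrichedBaseProb, goEnrichedOR = goEnrichedOR,
      seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nPairs, "pairs,",
      object@nSingletonA + object@nSingletonD, "singletons,",
      object@nScaffoldA + object@nScaffoldD, "scaffold genes\n")
  cat("  replicates:", object@replicates, " dispersion:", object@dispersion,
      " fold:", object@foldChange, " seed:", object@seed, "\n")
})

# mode -> (parental state, progeny state)
.MODE_PARENT <- c("A>D", "A<D", "A=D", "A>D", "A<D", "A=D", "A=D", "A>D", "A<D")
.MODE_PROGENY <- c("A>D", "A<D", "A=D", "A=D", "A=D", "A>D", "A<D", "A<D", "A>D")

.heGRanges <- function(heRegions) {
  if (nrow(heRegions) == 0)
    return(GRanges())
  gr <- GRanges(heRegions$chrom,
                IRanges(heRegions$start + 1, heRegions$end))
  mcols(gr)$line <- heRegions$line
  mcols(gr)$multiplier <- heRegions$multiplier
  gr
}

#' Generate the synthetic gene catalogs, pair table and HE intervals
#'
#' Lays out genes at increasing positions along seven chromosomes per
#' subgenome (pair members at matching ranks, giving collinearity), adds
#' unpaired singletons and unplaced scaffold genes, assigns transcript
#' lengths so that exactly \code{round(lengthDisparityFraction * nPairs)}
#' pairs exceed the 10 percent length-disparity threshold, and returns the
#' HE intervals as a GRanges.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{catalog} (combined GRanges, names =
#'   gene ids, mcols subgenome and transcript_length), \code{catalogA},
#'   \code{catalogD}, \code{pairs} (\linkS4class{HomoeologPairs}) and
#'   \code{heRegions} (GRanges with mcols line, multiplier).
#' @examples
#' cat <- generateCatalog(simConfig(nPairs = 50, seed = 1))
#' cat$pairs
#' @export
generateCatalog <- function(config) {
  validObject(config)
  set.seed(deriveSeed(config@seed, 1L))
  np <- config@nPairs

  idA <- sprintf("GA%05d", seq_len(np + config@nSingletonA +
                                     config@nScaffoldA))
  idD <- sprintf("GD%05d", seq_len(np + config@nSingletonD +
                                     config@nScaffoldD))

  # transcript lengths; a deterministic, evenly spread subset of pairs
  # violates the 10% disparity rule
  lenA <- sample(500:3000, np, replace = TRUE)
  k <- round(config@lengthDisparityFraction * np)
  vio <- rep(FALSE, np)
  if (k > 0) vio[floor(seq(1, np, length.out = k))] <- TRUE
  lenD <- ifelse(vio, round(lenA * 1.3),
                 round(lenA * (1 + runif(np, -0.04, 0.04))))
  lenSingA <- sample(500:3000, config@nSingletonA + config@nScaffoldA,
                     replace = TRUE)
  lenSingD <- sample(500:3000, config@nSingletonD + config@nScaffoldD,
                     replace = TRUE)

  place <- function(nPlaced, nScaffold, chromLength, suffix, lens) {
    chromIdx <- ((seq_len(nPlaced) - 1L) %% config@nChrom) + 1L
    pos <- integer(nPlaced)
    for (c in seq_len(config@nChrom)) {
      on <- which(chromIdx == c)
      m <- length(on)
      if (m) pos[on] <- round(chromLength * seq_len(m) / (m + 1))
    }
    chrom <- c(sprintf("Chr%d%s", chromIdx, suffix),
               rep(.UNPLACED, nScaffold))
    start <- c(pos, rep(1L, nScaffold))
    end <- c(pos + 1999L, pmax(1L, lens[nPlaced + seq_len(nScaffold)]))
    GRanges(chrom, IRanges(start, end))
  }
  nPlacedA <- np + config@nSingletonA
  nPlacedD <- np + config@nSingletonD
  grA <- place(nPlacedA, config@nScaffoldA, config@chromLengthA, "A",
               c(lenA, lenSingA))
  grD <- place(nPlacedD, config@nScaffoldD, config@chromLengthD, "D",
               c(lenD, lenSingD))
  names(grA) <- idA
  names(grD) <- idD
  mcols(grA)$subgenome <- "A"
  mcols(grD)$subgenome <- "D"
  mcols(grA)$transcript_length <- as.integer(c(lenA, lenSingA))
  mcols(grD)$transcript_length <- as.integer(c(lenD, lenSingD))

  pairs <- HomoeologPairs(idA[seq_len(np)], idD[seq_len(np)])
  catalog <- suppressWarnings(c(grA, grD))
  list(catalog = catalog, catalogA = grA, catalogD = grD, pairs = pairs,
       heRegions = .heGRanges(config@heRegions))
}

#' TruthTable: the planted ground truth of a simulated study
#'
#' @slot pairTruth DataFrame, one row per pair x condition: planted parental
#'   and progeny ratio states, mode (1-9), linear fold magnitude (1 exactly
#'   for mode 3), and per-copy change of the progeny relative to Mix
#'   (up / down / unchanged per copy).
#' @slot rates matrix (genes x conditions) of parent-scale baseline
#'   expression rates; Mix samples expect half of these at library factor 1.
#' @slot progenyMult matrix (genes x conditions): per-copy multiplicative
#'   change of the tetraploid relative to Mix.
#' @slot heMult named vector: X190 copy-number multiplier per gene.
#' @slot modeProportions the planted mode proportion matrix.
#' @export
setClass("TruthTable", representation(
  pairTruth = "DataFrame", rates = "matrix", progenyMult = "matrix",
  heMult = "numeric", modeProportions = "matrix"))

.validTruthTable <- function(object) {
  msg <- NULL
  pt <- object@pairTruth
  if (nrow(pt)) {
    eq <- pt$mode == 3L
    if (!all(pt$fold[eq] == 1))
      msg <- c(msg, "fold must be 1 when the planted state is A=D")
    if (any(pt$fold[!eq] <= 1))
      msg <- c(msg, "fold must exceed 1 for unequal states")
  }
  if (any(object@heMult < 0))
    msg <- c(msg, "copy-number multipliers must be non-negative")
  if (any(abs(rowSums(object@modeProportions) - 1) > 1e-8))
    msg <- c(msg, "mode proportions must sum to 1")
  if (is.null(msg)) TRUE else msg
}
setValidity("TruthTable", .validTruthTable)

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable:", nrow(object@rates), "genes,",
      length(unique(object@pairTruth$pairId)), "pairs,",
      ncol(object@rates), "conditions\n")
  print(table(mode = object@pairTruth$mode))
})

#' @describeIn TruthTable planted pair-level truth as a data.frame.
#' @param x a TruthTable.
#' @export
pairTruth <- function(x) as.data.frame(x@pairTruth)

#' Plan the ground truth of a simulated study
#'
#' Samples a mode per pair and condition from the configured proportions,
#' derives parental rates (geometric split of a log-uniform baseline by
#' \code{sqrt(foldChange)}) and per-copy progeny changes that realize each
#' mode: convergent and divergent modes are realized by changing a single
#' copy (which copy is Bernoulli with \code{changedCopyBias}), reversed
#' modes by opposite changes in both copies. Singleton genes are planted as
#' progeny-vs-Mix DEGs at the configured per-subgenome fractions, with an
#' optional chromosome-specific burst. X190 copy-number multipliers follow
#' the HE intervals.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param cat output of \code{\link{generateCatalog}}.
#' @return a \linkS4class{TruthTable}.
#' @export
planTruth <- function(config, cat) {
  set.seed(deriveSeed(config@seed, 2L))
  conds <- config@conditions
  genes <- names(cat$catalog)
  ng <- length(genes)
  np <- config@nPairs
  pt <- pairTable(cat$pairs)
  f <- config@foldChange
  sg <- mcols(cat$catalog)$subgenome
  chrom <- as.character(seqnames(cat$catalog))

  rates <- matrix(0, ng, length(conds), dimnames = list(genes, conds))
  pmult <- matrix(1, ng, length(conds), dimnames = list(genes, conds))
  truthRows <- vector("list", length(conds))

  lb <- log(config@baselineRange)
  singles <- setdiff(genes, c(pt$aGene, pt$dGene))

  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    mode <- sample.int(9L, np, replace = TRUE,
                       prob = config@modeProportions[cond, ])
    b <- exp(runif(np, lb[1], lb[2]))
    pState <- .MODE_PARENT[mode]
    gState <- .MODE_PROGENY[mode]
    rA <- b * ifelse(pState == "A>D", sqrt(f),
                     ifelse(pState == "A<D", 1 / sqrt(f), 1))
    rD <- b * ifelse(pState == "A>D", 1 / sqrt(f),
                     ifelse(pState == "A<D", sqrt(f), 1))
    # per-copy changes realizing the progeny state
    dA <- rep(1, np)
    dD <- rep(1, np)
    onD <- runif(np) < config@changedCopyBias  # the changed copy, when one
    i <- mode == 4L; dA[i & !onD] <- 1 / f; dD[i & onD] <- f
    i <- mode == 5L; dA[i & !onD] <- f; dD[i & onD] <- 1 / f
    i <- mode == 6L; dA[i & !onD] <- f; dD[i & onD] <- 1 / f
    i <- mode == 7L; dA[i & !onD] <- 1 / f; dD[i & onD] <- f
    i <- mode == 8L; dA[i] <- 1 / f; dD[i] <- f
    i <- mode == 9L; dA[i] <- f; dD[i] <- 1 / f

    rates[pt$aGene, ci] <- rA
    rates[pt$dGene, ci] <- rD
    pmult[pt$aGene, ci] <- dA
    pmult[pt$dGene, ci] <- dD

    # singleton genes: baseline rate plus optional planted DEG status
    rates[singles, ci] <- exp(runif(length(singles), lb[1], lb[2]))
    frac <- ifelse(sg[match(singles, genes)] == "A",
                   config@degFractionA, config@degFractionD)
    if (length(config@burstChrom) && cond %in% config@burstCondition)
      frac[chrom[match(singles, genes)] %in% config@burstChrom] <-
        config@burstFraction
    isDeg <- runif(length(singles)) < frac
    up <- runif(length(singles)) < 0.5
    pmult[singles, ci] <- ifelse(isDeg, ifelse(up, f, 1 / f), 1)

    lab <- function(d) ifelse(d > 1, "up", ifelse(d < 1, "down", "unchanged"))
    truthRows[[ci]] <- DataFrame(
      pairId = pt$pairId, condition = cond, parentState = pState,
      progenyState = gState, mode = mode,
      fold = ifelse(mode == 3L, 1, f), deltaA = lab(dA), deltaD = lab(dD))
  }

  heMult <- rep(1, ng)
  names(heMult) <- genes
  if (length(cat$heRegions)) {
    hits <- findOverlaps(cat$catalog, cat$heRegions, minoverlap = 1L)
    heMult[S4Vectors::queryHits(hits)] <-
      mcols(cat$heRegions)$multiplier[S4Vectors::subjectHits(hits)]
  }

  new("TruthTable", pairTruth = do.call(rbind, truthRows), rates = rates,
      progenyMult = pmult, heMult = heMult,
      modeProportions = config@modeProportions)
}

#' Simulate the count matrix and sample design
#'
#' Counts are NB(mean = rate x library factor x copy-number multiplier,
#' dispersion = configured alpha); dispersion 0 degenerates to Poisson.
#' Pure-parent samples express only their own subgenome; Mix samples expect
#' half the pure-parent rate per gene (equal-mass mixing at fixed depth);
#' tetraploid samples express both copies at the Mix rate times the planted
#' per-copy change; X190 additionally applies HE copy-number multipliers.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth a \linkS4class{TruthTable} from \code{\link{planTruth}}.
#' @param cat catalog list from \code{\link{generateCatalog}}.
#' @return a \linkS4class{HomoeoExperiment}.
#' @export
simulateCounts <- function(config, truth, cat) {
  set.seed(deriveSeed(config@seed, 3L))
  genes <- rownames(truth@rates)
  sg <- mcols(cat$catalog)$subgenome[match(genes, names(cat$catalog))]
  conds <- config@conditions
  design <- expand.grid(replicate = seq_len(config@replicates),
                        condition = conds, genotype = config@genotypes,
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%s_r%d", design$genotype, design$condition,
                           design$replicate)
  design <- design[, c("sample", "genotype", "condition", "replicate")]
  ns <- nrow(design)
  libf <- exp(runif(ns, log(config@libSizeRange[1]),
                    log(config@libSizeRange[2])))

  counts <- matrix(0L, length(genes), ns,
                   dimnames = list(genes, design$sample))
  for (j in seq_len(ns)) {
    cond <- design$condition[j]
    base <- truth@rates[, cond]
    mu <- switch(design$genotype[j],
      parentA = ifelse(sg == "A", base, 0),
      parentD = ifelse(sg == "D", base, 0),
      Mix = 0.5 * base,
      EUP = 0.5 * base * truth@progenyMult[, cond],
      X190 = 0.5 * base * truth@progenyMult[, cond] * truth@heMult,
      stopf("unknown genotype '%s'", design$genotype[j]))
    mu <- mu * libf[j]
    counts[, j] <- if (config@dispersion == 0) rpois(length(mu), mu)
                   else rnbinom(length(mu), size = 1 / config@dispersion,
                                mu = mu)
  }
  storage.mode(counts) <- "integer"
  HomoeoExperiment(counts, design, cat$catalog)
}

#' Generate a synthetic GO annotation map
#'
#' Background terms are assigned at random (per-term Bernoulli probability
#' drawn from \code{goBaseProbRange}); one designated term is preferentially
#' assigned to genes planted as changed (progeny-vs-Mix, first condition) at
#' the configured odds ratio.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth a \linkS4class{TruthTable}.
#' @param cat catalog list.
#' @param seed optional override of the derived GO-stage seed.
#' @return data.frame (gene_id, term_id) with attribute
#'   \code{enrichedTerm} naming the planted term.
#' @export
generateGOMap <- function(config, truth, cat, seed = NULL) {
  set.seed(if (is.null(seed)) deriveSeed(config@seed, 4L)
           else as.integer(seed))
  genes <- names(cat$catalog)
  nT <- config@goTerms
  terms <- sprintf("GO:%07d", seq_len(nT))
  enriched <- terms[1]
  basep <- runif(nT, config@goBaseProbRange[1], config@goBaseProbRange[2])
  changed <- truth@progenyMult[, 1] != 1
  p0 <- config@goEnrichedBaseProb
  odds <- p0 / (1 - p0) * config@goEnrichedOR
  p1 <- odds / (1 + odds)

  out <- vector("list", nT)
  for (t in seq_len(nT)) {
    p <- if (terms[t] == enriched) ifelse(changed, p1, p0) else basep[t]
    hit <- runif(length(genes)) < p
    if (any(hit))
      out[[t]] <- data.frame(gene_id = genes[hit], term_id = terms[t],
                             stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  attr(map, "enrichedTerm") <- enriched
  map
}

#' Simulate a complete study
#'
#' Runs catalog generation, truth planning, count simulation and GO-map
#' generation from one config; each stage uses its own seed sub-stream
#' derived from the master seed, so identical configs give identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{config}, \code{catalog},
#'   \code{catalogA}, \code{catalogD}, \code{pairs}, \code{heRegions},
#'   \code{truth}, \code{experiment}, \code{goMap}, \code{enrichedTerm}.
#' @examples
#' std <- simulateHomoeoStudy(simConfig(nPairs = 30, seed = 42))
#' head(pairTruth(std$truth))
#' @export
simulateHomoeoStudy <- function(config) {
  cat <- generateCatalog(config)
  truth <- planTruth(config, cat)
  hex <- simulateCounts(config, truth, cat)
  goMap <- generateGOMap(config, truth, cat)
  list(config = config, catalog = cat$catalog, catalogA = cat$catalogA,
       catalogD = cat$catalogD, pairs = cat$pairs,
       heRegions = cat$heRegions, truth = truth, experiment = hex,
       goMap = goMap, enrichedTerm = attr(goMap, "enrichedTerm"))
}
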