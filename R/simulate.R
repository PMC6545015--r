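#' Simulate a gene annotation (synthetic genome)
#'
#' Builds a toy genome: \code{nChromosomes} chromosomes carrying
#' \code{genesPerChromosome} genes each at strictly increasing, unique start
#' coordinates. Optionally appends a dedicated mitochondrial
#' pseudo-chromosome (\code{"MT"}) whose genes are flagged \code{mito = TRUE}
#' and excluded from sliding-window copy-number estimation.
#'
#' @param nChromosomes number of (nuclear) chromosomes, >= 1.
#' @param genesPerChromosome genes per chromosome; a single integer or one
#'   per chromosome.
#' @param seed integer seed; the same seed reproduces the annotation
#'   bit-identically.
#' @param nMitoGenes number of mitochondrial genes on the \code{"MT"}
#'   pseudo-chromosome (0 = none).
#' @param chromosomeLength coordinate space per chromosome from which gene
#'   starts are drawn.
#' @return a named \link[GenomicRanges]{GRanges} (names are gene ids) with a
#'   logical metadata column \code{mito}, sorted by (chromosome, start).
#' @examples
#' gn <- simulateGenome(2, 5, seed = 1)
#' table(GenomicRanges::seqnames(gn))
#' @export
simulateGenome <- function(nChromosomes, genesPerChromosome, seed = NULL,
                           nMitoGenes = 0L, chromosomeLength = 2e8) {
  if (!is.numeric(nChromosomes) || nChromosomes < 1) {
    stop("'nChromosomes' must be >= 1")
  }
  if (any(genesPerChromosome < 1)) {
    stop("'genesPerChromosome' must be >= 1")
  }
  nChromosomes <- as.integer(nChromosomes)
  npc <- rep_len(as.integer(genesPerChromosome), nChromosomes)
  .withSeed(seed, {
    chroms <- paste0("chr", seq_len(nChromosomes))
    sn <- rep(chroms, npc)
    starts <- unlist(lapply(npc, function(n) {
      sort(sample.int(chromosomeLength, n))
    }), use.names = FALSE)
    mito <- rep(FALSE, sum(npc))
    if (nMitoGenes > 0) {
      sn <- c(sn, rep("MT", nMitoGenes))
      starts <- c(starts, sort(sample.int(20000L, nMitoGenes)))
      mito <- c(mito, rep(TRUE, nMitoGenes))
      chroms <- c(chroms, "MT")
    }
    gr <- GenomicRanges::GRanges(
      seqnames = factor(sn, levels = chroms),
      ranges = IRanges::IRanges(start = starts, width = 1L),
      mito = mito)
    names(gr) <- sprintf("gene_%05d", seq_along(gr))
    gr
  })
}

#' Simulate per-cell whole-chromosome karyotypes under mis-segregation
#'
#' Models chromosomal instability as independent whole-chromosome
#' mis-segregation: each (cell, chromosome) pair deviates from the base
#' ploidy by +1 or -1 copy with probability \code{missegregationRate},
#' independently across cells and chromosomes; deviations leaving the
#' allowed range \code{[0, maxCopies]} are resampled. Optional clonal events
#' model population-level aneuploidies (e.g. a chromosome gained by most
#' cells of a tumor line): each listed chromosome is first set to the given
#' copy number in a random \code{clonalFraction} of cells, then random
#' mis-segregation is applied on top.
#'
#' Mitochondrial pseudo-chromosomes (\code{"MT"}) always stay at base ploidy.
#'
#' @param genome annotation from [simulateGenome()] (its chromosome set
#'   defines the karyotype columns).
#' @param nCells number of cells, >= 1.
#' @param missegregationRate per-(cell, chromosome) deviation probability in
#'   \code{[0, 1]}.
#' @param maxCopies maximum copy number permitted.
#' @param basePloidy euploid copy number (default 2).
#' @param clonalEvents optional named integer vector, chromosome -> copy
#'   number, applied before random mis-segregation.
#' @param clonalFraction fraction of cells carrying the clonal events.
#' @param seed integer seed.
#' @return integer matrix, cells in rows and chromosomes in columns, with a
#'   \code{"basePloidy"} attribute.
#' @examples
#' gn <- simulateGenome(4, 10, seed = 1)
#' k <- simulateKaryotypes(gn, nCells = 5, missegregationRate = 0, seed = 2)
#' all(k == 2)
#' @export
simulateKaryotypes <- function(genome, nCells, missegregationRate = 0.3,
                               maxCopies = 4L, basePloidy = 2L,
                               clonalEvents = NULL, clonalFraction = 0.8,
                               seed = NULL) {
  if (nCells < 1) stop("'nCells' must be >= 1")
  if (!is.numeric(missegregationRate) || missegregationRate < 0 ||
      missegregationRate > 1) {
    stop("'missegregationRate' must be in [0, 1]")
  }
  chroms <- levels(GenomicRanges::seqnames(genome))
  nuclear <- setdiff(chroms, "MT")
  .withSeed(seed, {
    k <- matrix(as.integer(basePloidy), nrow = nCells, ncol = length(chroms),
                dimnames = list(sprintf("cell_%04d", seq_len(nCells)), chroms))
    if (!is.null(clonalEvents)) {
      bad <- setdiff(names(clonalEvents), nuclear)
      if (length(bad)) stop("unknown chromosome in clonalEvents: ",
                            paste(bad, collapse = ", "))
      carriers <- stats::runif(nCells) < clonalFraction
      for (ch in names(clonalEvents)) {
        k[carriers, ch] <- as.integer(clonalEvents[[ch]])
      }
    }
    if (missegregationRate > 0 && length(nuclear)) {
      hit <- matrix(stats::runif(nCells * length(nuclear)) <
                      missegregationRate,
                    nrow = nCells)
      for (j in seq_along(nuclear)) {
        idx <- which(hit[, j])
        for (i in idx) {
          repeat {
            cand <- k[i, nuclear[j]] + sample(c(-1L, 1L), 1L)
            if (cand >= 0L && cand <= maxCopies) {
              k[i, nuclear[j]] <- cand
              break
            }
          }
        }
      }
    }
    attr(k, "basePloidy") <- as.integer(basePloidy)
    k
  })
}

#' Configuration for the count simulator
#'
#' Bundles the generative parameters of [simulateCounts()]. Per-gene
#' baseline means are log-normal; counts are negative binomial with a shared
#' dispersion (size) parameter, scaled by a per-cell log-normal size factor,
#' and thinned by an extra dropout probability to emulate zero inflation.
#'
#' @param baselineMeanlog,baselineSdlog log-normal parameters of per-gene
#'   baseline mean expression (defaults give a median of ~20 counts).
#' @param bufferedFraction fraction of non-mitochondrial genes whose
#'   expression is buffered against (i.e. ignores) copy number.
#' @param groupEffects named numeric vector of log2 effect sizes applied to
#'   the given genes in test-labelled cells only.
#' @param libsizeSdlog sdlog of per-cell log-normal size factors.
#' @param dispersion negative-binomial size parameter (> 0); larger is
#'   closer to Poisson.
#' @param dropout zero-inflation magnitude: the extra dropout probability
#'   for an entry with expected count near 0. Dropout is mean-dependent,
#'   \code{p = dropout * exp(-dropoutDecay * mu)}, so well-expressed genes
#'   are essentially never zeroed while lowly expressed genes gain extra
#'   zeros; 0 disables zero inflation entirely.
#' @param dropoutDecay decay rate of the dropout probability per unit of
#'   expected count.
#' @param bufferedGenes optional explicit character vector of buffered gene
#'   ids (overrides \code{bufferedFraction} sampling).
#' @return a list of class \code{"simTruthConfig"}.
#' @export
simTruthConfig <- function(baselineMeanlog = 3, baselineSdlog = 1,
                           bufferedFraction = 0.2, groupEffects = NULL,
                           libsizeSdlog = 0.2, dispersion = 10,
                           dropout = 0.5, dropoutDecay = 0.3,
                           bufferedGenes = NULL) {
  if (dispersion <= 0) stop("'dispersion' must be > 0")
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  if (dropoutDecay < 0) stop("'dropoutDecay' must be >= 0")
  if (bufferedFraction < 0 || bufferedFraction > 1) {
    stop("'bufferedFraction' must be in [0, 1]")
  }
  structure(list(baselineMeanlog = baselineMeanlog,
                 baselineSdlog = baselineSdlog,
                 bufferedFraction = bufferedFraction,
                 groupEffects = groupEffects,
                 libsizeSdlog = libsizeSdlog,
                 dispersion = dispersion,
                 dropout = dropout,
                 dropoutDecay = dropoutDecay,
                 bufferedGenes = bufferedGenes),
            class = "simTruthConfig")
}

#' Simulate a single-cell count matrix with known copy-number truth
#'
#' The expected expression of a non-buffered gene g in cell k is
#' \code{baseline_g * (copyNumber / basePloidy) * 2^(groupEffect_g) *
#' sizeFactor_k}, where the group effect applies only in test-labelled
#' cells; buffered genes use a copy ratio of exactly 1 (dosage
#' compensation). Counts are negative binomial with the configured
#' dispersion, then thinned by the dropout probability. All ground truth
#' (karyotypes, buffered genes, planted effects, seed) is recorded in the
#' metadata of the returned object.
#'
#' @param genome annotation from [simulateGenome()].
#' @param karyotype cells-by-chromosomes integer matrix from
#'   [simulateKaryotypes()].
#' @param config a [simTruthConfig()].
#' @param labels per-cell label, \code{"reference"} or \code{"test"};
#'   default all \code{"test"}.
#' @param seed integer seed.
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with assay
#'   \code{"counts"}, rowRanges = \code{genome} (plus \code{buffered} and
#'   \code{groupEffect} columns), colData columns \code{label} and
#'   \code{trueSizeFactor}, and \code{metadata()$truth} containing the
#'   simulation ground truth.
#' @export
simulateCounts <- function(genome, karyotype, config = simTruthConfig(),
                           labels = NULL, seed = NULL) {
  stopifnot(inherits(config, "simTruthConfig"))
  nCells <- nrow(karyotype)
  nGenes <- length(genome)
  if (is.null(labels)) labels <- rep("test", nCells)
  labels <- .checkLabels(labels, nCells)
  basePloidy <- attr(karyotype, "basePloidy")
  if (is.null(basePloidy)) basePloidy <- 2L
  geneChrom <- as.character(GenomicRanges::seqnames(genome))
  geneIds <- names(genome)
  .withSeed(seed, {
    baseline <- stats::rlnorm(nGenes, config$baselineMeanlog,
                              config$baselineSdlog)
    names(baseline) <- geneIds
    nonMito <- geneIds[!genome$mito]
    if (!is.null(config$bufferedGenes)) {
      buffered <- intersect(config$bufferedGenes, geneIds)
      if (length(buffered) < length(config$bufferedGenes)) {
        stop("bufferedGenes contains ids not in the genome")
      }
    } else {
      buffered <- sample(nonMito,
                         round(config$bufferedFraction * length(nonMito)))
    }
    effects <- stats::setNames(numeric(nGenes), geneIds)
    if (!is.null(config$groupEffects)) {
      bad <- setdiff(names(config$groupEffects), geneIds)
      if (length(bad)) stop("groupEffects contains unknown genes: ",
                            paste(bad, collapse = ", "))
      effects[names(config$groupEffects)] <- config$groupEffects
    }
    sf <- stats::rlnorm(nCells, 0, config$libsizeSdlog)
    sf <- sf / mean(sf)
    # copy ratio per gene x cell; buffered and mito genes stay at 1
    ratio <- t(karyotype[, geneChrom, drop = FALSE]) / basePloidy
    ratio[geneIds %in% buffered | genome$mito, ] <- 1
    isTest <- labels == "test"
    mu <- baseline * ratio *
      2^(outer(effects, as.numeric(isTest))) *
      rep(sf, each = nGenes)
    counts <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                    size = config$dispersion),
                     nrow = nGenes)
    if (config$dropout > 0) {
      pDrop <- config$dropout * exp(-config$dropoutDecay * mu)
      keep <- matrix(stats::runif(length(mu)) >= as.numeric(pDrop),
                     nrow = nGenes)
      counts <- counts * keep
    }
    dimnames(counts) <- list(geneIds, rownames(karyotype))
    rr <- genome
    rr$buffered <- geneIds %in% buffered
    rr$groupEffect <- unname(effects)
    independentDe <- names(config$groupEffects)[
      names(config$groupEffects) %in% buffered]
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      rowRanges = rr,
      colData = S4Vectors::DataFrame(label = labels, trueSizeFactor = sf,
                                     row.names = colnames(counts)))
    metadata(sce)$truth <- list(
      karyotype = karyotype,
      basePloidy = basePloidy,
      baseline = baseline,
      bufferedGenes = sort(buffered),
      groupEffects = config$groupEffects,
      independentDeGenes = independentDe,
      seed = seed,
      config = config)
    sce
  })
}

#' Simulate a reference-plus-CIN single-cell experiment
#'
#' Convenience wrapper that draws a diploid reference population and a
#' chromosomally unstable test population on the same synthetic genome and
#' returns one combined count experiment, mirroring a diploid control line
#' profiled alongside an unstable tumor line.
#'
#' @inheritParams simulateKaryotypes
#' @inheritParams simulateCounts
#' @param nRef,nTest reference (diploid) and test (CIN) cell numbers.
#' @return see [simulateCounts()].
#' @export
simulateCinExperiment <- function(genome, nRef = 52, nTest = 69,
                                  missegregationRate = 0.3, maxCopies = 4L,
                                  basePloidy = 2L, clonalEvents = NULL,
                                  clonalFraction = 0.8,
                                  config = simTruthConfig(), seed = NULL) {
  .withSeed(seed, {
    chroms <- levels(GenomicRanges::seqnames(genome))
    kRef <- matrix(as.integer(basePloidy), nrow = nRef, ncol = length(chroms),
                   dimnames = list(sprintf("ref_%04d", seq_len(nRef)), chroms))
    kTest <- simulateKaryotypes(genome, nTest,
                                missegregationRate = missegregationRate,
                                maxCopies = maxCopies,
                                basePloidy = basePloidy,
                                clonalEvents = clonalEvents,
                                clonalFraction = clonalFraction)
    rownames(kTest) <- sprintf("test_%04d", seq_len(nTest))
    k <- rbind(kRef, kTest)
    attr(k, "basePloidy") <- as.integer(basePloidy)
    simulateCounts(genome, k, config = config,
                   labels = rep(c("reference", "test"), c(nRef, nTest)))
  })
}

#' Simulate a bulk tumor cohort with grade and survival structure
#'
#' Each sample carries a standard-normal latent score. Expression of
#' up-weighted signature genes increases with the score, down-weighted
#' genes decrease with it, background genes are pure noise. Survival times
#' are exponential with log-hazard \code{-hazardCoefficient * latentScore}
#' (a positive coefficient makes high-scoring samples live longer), with
#' independent exponential censoring. Ordinal grade is assigned by latent
#' score tertiles with high scores mapping to low grade.
#'
#' @param weights a \linkS4class{CiSignature} defining the signature genes.
#' @param nSamples number of samples, >= 4.
#' @param hazardCoefficient effect of the latent score on log hazard.
#' @param effectSize expression shift per unit latent score on signature
#'   genes.
#' @param noiseSd residual expression noise standard deviation.
#' @param nNoiseGenes number of background (non-signature) genes.
#' @param baselineHazard baseline event rate (1 / mean survival time at
#'   latent score 0).
#' @param censorRate censoring rate as a multiple of the baseline hazard;
#'   0 disables censoring.
#' @param seed integer seed.
#' @return a list with elements \code{expression} (genes x samples matrix),
#'   \code{clinical} (data.frame: sample, grade, time, event) and
#'   \code{latentScore} (named numeric).
#' @export
simulateCohort <- function(weights, nSamples = 200, hazardCoefficient = 0.5,
                           effectSize = 1, noiseSd = 1, nNoiseGenes = 500,
                           baselineHazard = 0.1, censorRate = 0.25,
                           seed = NULL) {
  stopifnot(methods::is(weights, "CiSignature"))
  if (nSamples < 4) stop("'nSamples' must be >= 4 (cannot dichotomize)")
  up <- wPlus(weights)
  dn <- wMinus(weights)
  .withSeed(seed, {
    samples <- sprintf("sample_%04d", seq_len(nSamples))
    latent <- stats::setNames(stats::rnorm(nSamples), samples)
    genes <- c(up, dn,
               if (nNoiseGenes > 0) sprintf("noise_%05d", seq_len(nNoiseGenes)))
    direction <- c(rep(1, length(up)), rep(-1, length(dn)),
                   rep(0, nNoiseGenes))
    expr <- outer(direction * effectSize, latent) +
      matrix(stats::rnorm(length(genes) * nSamples, sd = noiseSd),
             nrow = length(genes))
    dimnames(expr) <- list(genes, samples)
    hazard <- baselineHazard * exp(-hazardCoefficient * latent)
    tEvent <- stats::rexp(nSamples, rate = hazard)
    if (censorRate > 0) {
      tCens <- stats::rexp(nSamples, rate = baselineHazard * censorRate)
    } else {
      tCens <- rep(Inf, nSamples)
    }
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
    tert <- stats::quantile(latent, c(1 / 3, 2 / 3), type = 1)
    grade <- cut(latent, c(-Inf, tert, Inf),
                 labels = c("IV", "III", "I/II"))
    grade <- factor(as.character(grade), levels = c("I/II", "III", "IV"),
                    ordered = TRUE)
    list(expression = expr,
         clinical = data.frame(sample = samples, grade = grade,
                               time = time, event = event,
                               stringsAsFactors = FALSE),
         latentScore = latent)
  })
}
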