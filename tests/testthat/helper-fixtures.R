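# Fixtures shared across test files; everything is generated in code.

# A SingleCellExperiment from a plain matrix, with a one-chromosome toy
# annotation (optionally flagging some genes mitochondrial).
toySCE <- function(counts, labels = rep("test", ncol(counts)),
                   mito = rep(FALSE, nrow(counts))) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  }
  ann <- GenomicRanges::GRanges(
    seqnames = factor(ifelse(mito, "MT", "chr1"),
                      levels = c("chr1", if (any(mito)) "MT")),
    ranges = IRanges::IRanges(start = seq_len(nrow(counts)) * 100L,
                              width = 1L),
    mito = mito)
  names(ann) <- rownames(counts)
  makeCountExperiment(counts, ann, labels)
}

# An annotation with explicit per-gene chromosome/position, for window tests.
toyAnnotation <- function(chrom, start = NULL, ids = NULL,
                          mito = rep(FALSE, length(chrom))) {
  if (is.null(start)) {
    start <- unlist(lapply(table(factor(chrom, levels = unique(chrom))),
                           seq_len)) * 100L
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = unique(chrom)),
    ranges = IRanges::IRanges(start = start, width = 1L),
    mito = mito)
  names(gr) <- if (is.null(ids)) sprintf("g%03d", seq_along(gr)) else ids
  gr
}

# Brute-force sliding-window oracle: per-gene loop over same-chromosome
# neighbors, truncated windows, actual-count denominator, no thresholding.
bruteForceECN <- function(X, chrom, radius) {
  out <- X * NA_real_
  for (i in seq_len(nrow(X))) {
    idx <- which(chrom == chrom[i])
    pos <- match(i, idx)
    win <- idx[max(1, pos - radius):min(length(idx), pos + radius)]
    out[i, ] <- colMeans(X[win, , drop = FALSE])
  }
  out
}

# The standard recovery simulation: CIN test population with clonal
# chr1 gain / chr2 loss, planted buffered (CN-independent) DE genes.
recoverySim <- function(nRef = 60, nTest = 60, effect = 1.2, seed = 13) {
  gn <- simulateGenome(10, 100, seed = 11)
  ids <- names(gn)
  chrom <- as.character(GenomicRanges::seqnames(gn))
  set.seed(12)
  candidates <- sample(ids[!(chrom %in% c("chr1", "chr2"))], 150)
  bufferedOnly <- candidates[1:100]
  deUp <- candidates[101:130]
  deDn <- candidates[131:150]
  effects <- c(stats::setNames(rep(effect, 30), deUp),
               stats::setNames(rep(-effect, 20), deDn))
  cfg <- simTruthConfig(bufferedFraction = 0, groupEffects = effects,
                        bufferedGenes = c(bufferedOnly, deUp, deDn))
  sce <- simulateCinExperiment(gn, nRef = nRef, nTest = nTest,
                               missegregationRate = 0.3,
                               clonalEvents = c(chr1 = 4, chr2 = 1),
                               clonalFraction = 0.8, config = cfg,
                               seed = seed)
  list(sce = sce, genome = gn, deUp = deUp, deDn = deDn,
       truthCI = c(deUp, deDn),
       dosage = ids[chrom %in% c("chr1", "chr2") &
                      !(ids %in% c(bufferedOnly, deUp, deDn))])
}

# Run the ECN pipeline (normalize -> reference profile -> relative
# expression -> windows) on a simulated experiment, without QC filters.
runEcnPipeline <- function(sce, windowRadius = 50, zeroThreshold = 0.5) {
  sce <- normalizeCounts(sce)
  prof <- buildReferenceProfile(sce)
  X <- relativeExpression(sce, prof)
  estimateECN(X, SummarizedExperiment::rowRanges(sce),
              windowRadius = windowRadius, zeroThreshold = zeroThreshold)
}
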