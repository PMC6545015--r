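#' Build the diploid reference expression profile
#'
#' The reference profile is the per-gene geometric mean of normalized
#' expression across the reference (diploid) cells, computed with a
#' pseudocount so zero counts are admissible:
#' \code{profile_g = exp(mean(log(norm_gk + pseudocount)))}.
#'
#' @param x a SingleCellExperiment with a \code{"normcounts"} assay, or a
#'   normalized genes-by-cells matrix.
#' @param referenceCells cell ids (or logical/integer index) of the
#'   reference cells; defaults to cells with colData \code{label ==
#'   "reference"}.
#' @param pseudocount added to every value before the geometric mean
#'   (default 1).
#' @return a \linkS4class{ReferenceProfile}.
#' @examples
#' m <- matrix(c(0, 8), nrow = 1, dimnames = list("g1", c("a", "b")))
#' profileValues(buildReferenceProfile(m, c("a", "b")))  # 3
#' @export
buildReferenceProfile <- function(x, referenceCells = NULL, pseudocount = 1) {
  norm <- .assayOrMatrix(x, "normcounts")
  if (is.null(referenceCells)) {
    if (methods::is(x, "SummarizedExperiment") &&
        "label" %in% colnames(SummarizedExperiment::colData(x))) {
      referenceCells <- colnames(x)[
        SummarizedExperiment::colData(x)$label == "reference"]
    } else {
      stop("no reference cells: supply 'referenceCells' or a 'label' column")
    }
  }
  ref <- norm[, referenceCells, drop = FALSE]
  if (ncol(ref) < 2) stop("need at least 2 reference cells")
  values <- exp(rowMeans(log(ref + pseudocount)))
  methods::new("ReferenceProfile", values = values, pseudocount = pseudocount)
}

#' Relative expression against the diploid reference
#'
#' Per gene and cell, the log2 fold change of normalized expression over
#' the reference profile, using the profile's recorded pseudocount:
#' \code{X_gk = log2(norm_gk + pc) - log2(profile_g)}, followed by per-cell
#' median centering (each cell's median over genes is subtracted, so a
#' uniform global shift of a cell — e.g. a residual scaling difference —
#' is absorbed and the per-cell median of X is 0).
#'
#' @inheritParams buildReferenceProfile
#' @param profile a \linkS4class{ReferenceProfile}; its gene set must match
#'   the rows of \code{x}.
#' @return genes-by-cells numeric matrix of median-centered log2 ratios, in
#'   the row order of \code{x}.
#' @export
relativeExpression <- function(x, profile) {
  stopifnot(methods::is(profile, "ReferenceProfile"))
  norm <- .assayOrMatrix(x, "normcounts")
  miss <- setdiff(rownames(norm), names(profileValues(profile)))
  if (length(miss)) {
    stop("genes missing from the reference profile: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" ... (%d total)", length(miss)))
  }
  pv <- profileValues(profile)[rownames(norm)]
  X <- log2(norm + pseudocount(profile)) - log2(pv)
  med <- apply(X, 2, stats::median)
  sweep(X, 2, med)
}

# Truncated running mean of one chromosome block: interior genes average
# over 2r+1 neighbors, genes near the ends over however many neighbors
# exist (the denominator is the actual window size).
.windowMean <- function(Xc, radius) {
  n <- nrow(Xc)
  cs <- apply(Xc, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  lo <- pmax(seq_len(n) - radius, 1L)
  hi <- pmin(seq_len(n) + radius, n)
  top <- cs[hi, , drop = FALSE]
  bottom <- rbind(0, cs)[lo, , drop = FALSE]
  (top - bottom) / (hi - lo + 1L)
}

#' Estimate copy number by sliding-window averaging
#'
#' For each gene i of cell k (genes arranged by chromosomal coordinate),
#' the estimated copy number is the mean relative expression of the gene
#' and its \code{windowRadius} upstream and downstream neighbors on the
#' same chromosome:
#' \deqn{ECN_k(i) = \sum_{j=i-r}^{i+r} X_k(j) / (2r + 1)}
#' with the default radius r = 50 (101-gene windows). Windows never cross
#' chromosome boundaries and truncate near chromosome ends, where the
#' denominator is the actual neighbor count. To suppress noisy estimates,
#' every value with \code{|ECN| < zeroThreshold} is forced to exactly 0, so
#' ECN = 0 reads as diploid expression.
#'
#' @param X genes-by-cells relative expression matrix from
#'   [relativeExpression()] (rownames are gene ids).
#' @param annotation named GRanges giving each gene's chromosome and
#'   coordinate; must be sorted by (chromosome, start). Genes flagged
#'   \code{mito} are excluded from windows.
#' @param windowRadius neighbors on each side (default 50).
#' @param zeroThreshold dead-zone half-width on the log2 scale (default
#'   0.5); values with smaller magnitude are zeroed.
#' @return an \linkS4class{EcnExperiment} in genomic order.
#' @export
estimateECN <- function(X, annotation, windowRadius = 50, zeroThreshold = 0.5) {
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  if (is.null(names(annotation))) stop("'annotation' must be named by gene id")
  ord <- order(as.integer(GenomicRanges::seqnames(annotation)),
               GenomicRanges::start(annotation))
  if (!identical(ord, seq_along(annotation))) {
    stop("'annotation' is not sorted by (chromosome, coordinate); ",
         "sort it first (e.g. GenomicRanges::sort)")
  }
  mito <- annotation$mito
  if (is.null(mito)) mito <- rep(FALSE, length(annotation))
  ann <- annotation[!mito & names(annotation) %in% rownames(X)]
  missing <- setdiff(rownames(X), names(annotation))
  if (length(missing)) {
    stop("genes in X without annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  X <- X[names(ann), , drop = FALSE]
  chrom <- as.character(GenomicRanges::seqnames(ann))
  ecn <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ecn[idx, ] <- .windowMean(X[idx, , drop = FALSE], windowRadius)
  }
  empty <- setdiff(GenomeInfoDb::seqlevels(ann), c(unique(chrom), "MT"))
  if (length(empty)) warning("chromosomes without genes skipped: ",
                             paste(empty, collapse = ", "))
  ecn[abs(ecn) < zeroThreshold] <- 0
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(relexpr = X, ecn = ecn), rowRanges = ann)
  metadata(se)$windowRadius <- windowRadius
  metadata(se)$zeroThreshold <- zeroThreshold
  methods::new("EcnExperiment", se)
}

#' @rdname cinIndex
#' @export
setMethod("cinIndex", "EcnExperiment", function(x) {
  colMeans(abs(ecnMatrix(x)))
})

#' @rdname cinIndex
#' @export
setMethod("cinIndex", "matrix", function(x) {
  if (!nrow(x) || !ncol(x)) stop("empty ECN matrix")
  colMeans(abs(x))
})

#' Shuffle gene positions (negative control)
#'
#' Randomly permutes the gene-to-position mapping over the same position
#' set: the genomic positions stay fixed, the genes occupying them are
#' shuffled. After shuffling, a gene's expression is no longer associated
#' with its neighbors' copy number, so sliding-window copy-number signal —
#' and any population difference in the chromosomal instability index —
#' should vanish. Deterministic for a fixed seed.
#'
#' @param annotation named GRanges annotation.
#' @param seed integer seed.
#' @return the annotation with gene ids (and their per-gene metadata
#'   columns) permuted across positions.
#' @export
shuffleGenePositions <- function(annotation, seed = NULL) {
  .withSeed(seed, {
    perm <- sample(length(annotation))
    out <- annotation
    names(out) <- names(annotation)[perm]
    S4Vectors::mcols(out) <- S4Vectors::mcols(annotation)[perm, , drop = FALSE]
    out
  })
}

#' Call per-cell chromosome-level gains and losses
#'
#' Averages ECN over the genes of each chromosome in each cell and calls a
#' loss when the mean is below \code{-cutoff}, a gain when above
#' \code{+cutoff}, neutral otherwise. A whole-chromosome gain from 2 to 4
#' copies sits near mean ECN +1 (log2 of the copy ratio), a loss to 1 copy
#' near -1.
#'
#' @param ecn an \linkS4class{EcnExperiment}.
#' @param cutoff call threshold on mean chromosome ECN (default 0.25).
#' @return a \link[S4Vectors]{DataFrame} with columns \code{cell},
#'   \code{chromosome}, \code{meanEcn} and \code{call} (loss/neutral/gain).
#' @export
callChromosomeEvents <- function(ecn, cutoff = 0.25) {
  stopifnot(methods::is(ecn, "EcnExperiment"))
  e <- ecnMatrix(ecn)
  chrom <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(ecn)))
  chroms <- unique(chrom)
  means <- do.call(rbind, lapply(chroms, function(ch) {
    colMeans(e[chrom == ch, , drop = FALSE])
  }))
  rownames(means) <- chroms
  long <- DataFrame(
    cell = rep(colnames(e), each = length(chroms)),
    chromosome = rep(chroms, times = ncol(e)),
    meanEcn = as.numeric(means))
  long$call <- factor(ifelse(long$meanEcn < -cutoff, "loss",
                             ifelse(long$meanEcn > cutoff, "gain",
                                    "neutral")),
                      levels = c("loss", "neutral", "gain"))
  metadata(long)$cutoff <- cutoff
  long
}

#' Per-population fractions of chromosome-level calls
#'
#' @param calls output of [callChromosomeEvents()].
#' @param labels named per-cell labels (e.g. reference/test).
#' @return data.frame with the fraction of cells called loss / neutral /
#'   gain per (chromosome, label).
#' @export
chromosomeCallFractions <- function(calls, labels) {
  lab <- labels[calls$cell]
  tab <- table(chromosome = calls$chromosome, label = lab, call = calls$call)
  df <- as.data.frame(prop.table(tab, margin = c(1, 2)))
  names(df)[names(df) == "Freq"] <- "fraction"
  df
}
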