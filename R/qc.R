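#' QC / filtering configuration
#'
#' @param libsizeMadK cells with library size below
#'   \code{median - libsizeMadK * MAD} are removed (default 3).
#' @param mitoMadK cells with mitochondrial fraction above
#'   \code{median + mitoMadK * MAD} are removed (default 3).
#' @param lowAbundancePercentile genes whose mean normalized expression is
#'   at or below this percentile of per-gene means are removed (default 70,
#'   i.e. the top 30 percent of genes is retained); 0 disables the filter.
#' @param minNormLibsize second-pass cell filter on normalized library size
#'   over the retained genes: a number for an absolute cutoff, or
#'   \code{"auto"} for \code{median - 2 * MAD}.
#' @param maxZeroFraction cells whose fraction of zero counts among the
#'   retained genes exceeds this value are removed (default 0.25, i.e. a
#'   kept cell expresses at least 75 percent of the retained genes).
#' @return a list of class \code{"qcConfig"}.
#' @export
qcConfig <- function(libsizeMadK = 3, mitoMadK = 3,
                     lowAbundancePercentile = 70,
                     minNormLibsize = "auto", maxZeroFraction = 0.25) {
  if (lowAbundancePercentile < 0 || lowAbundancePercentile >= 100) {
    stop("'lowAbundancePercentile' must be in [0, 100)")
  }
  if (maxZeroFraction <= 0 || maxZeroFraction >= 1) {
    stop("'maxZeroFraction' must be in (0, 1)")
  }
  if (!identical(minNormLibsize, "auto") && !is.numeric(minNormLibsize)) {
    stop("'minNormLibsize' must be numeric or \"auto\"")
  }
  structure(list(libsizeMadK = libsizeMadK, mitoMadK = mitoMadK,
                 lowAbundancePercentile = lowAbundancePercentile,
                 minNormLibsize = minNormLibsize,
                 maxZeroFraction = maxZeroFraction),
            class = "qcConfig")
}

#' First-pass cell QC: library size and mitochondrial fraction
#'
#' Removes cells whose library size falls below
#' \code{median - k * MAD} of the library-size distribution, or whose
#' mitochondrial count fraction exceeds \code{median + k * MAD} of the
#' mitochondrial-fraction distribution. Both thresholds are computed on the
#' pre-filter distribution (the filter is applied once, not iterated). MAD
#' is the median absolute deviation with the usual 1.4826 consistency
#' constant.
#'
#' @param sce a \link[SingleCellExperiment]{SingleCellExperiment} with a
#'   \code{"counts"} assay; mitochondrial genes are identified by the
#'   logical \code{mito} rowData column when present.
#' @param config a [qcConfig()].
#' @return the filtered object; the filter report (thresholds, removed cell
#'   ids and reasons, kept/removed counts) is stored in
#'   \code{metadata()$qcCellFilter}.
#' @export
filterCellsQC <- function(sce, config = qcConfig()) {
  counts <- .assayOrMatrix(sce, "counts")
  if (ncol(counts) < 3) stop("need at least 3 cells for MAD-based QC")
  libsize <- colSums(counts)
  mito <- SummarizedExperiment::rowData(sce)$mito
  if (is.null(mito)) mito <- rep(FALSE, nrow(counts))
  mitoFrac <- if (any(mito)) {
    colSums(counts[mito, , drop = FALSE]) / pmax(libsize, 1)
  } else {
    rep(0, ncol(counts))
  }
  libThr <- stats::median(libsize) - config$libsizeMadK * stats::mad(libsize)
  mitoThr <- stats::median(mitoFrac) + config$mitoMadK * stats::mad(mitoFrac)
  lowLib <- libsize < libThr
  highMito <- mitoFrac > mitoThr
  drop <- lowLib | highMito
  if (all(drop)) stop("empty after QC: all cells removed by cell filters")
  report <- list(
    nInput = ncol(counts), nKept = sum(!drop), nRemoved = sum(drop),
    libsizeThreshold = libThr, mitoThreshold = mitoThr,
    removed = data.frame(
      cell = colnames(counts)[drop],
      lowLibsize = lowLib[drop],
      highMito = highMito[drop],
      row.names = NULL))
  out <- sce[, !drop]
  metadata(out)$qcCellFilter <- report
  out
}

#' Normalize counts by per-cell size factors
#'
#' Size factors are scaled to mean 1 so normalized values stay on the scale
#' of the raw counts. \code{"libsize"} uses total counts per cell;
#' \code{"median_ratio"} uses the median ratio of each cell to the per-gene
#' geometric mean (computed over genes expressed in every cell), which is
#' robust to a minority of differentially expressed genes;
#' \code{"external"} accepts size factors computed elsewhere (e.g. pooled
#' deconvolution factors).
#'
#' @param sce a SingleCellExperiment with a \code{"counts"} assay.
#' @param method one of \code{"libsize"}, \code{"median_ratio"},
#'   \code{"external"}.
#' @param sizeFactors numeric vector of externally computed factors
#'   (required for \code{method = "external"}).
#' @return the object with an added \code{"normcounts"} assay and a
#'   \code{sizeFactor} colData column.
#' @export
normalizeCounts <- function(sce, method = c("libsize", "median_ratio",
                                            "external"),
                            sizeFactors = NULL) {
  method <- match.arg(method)
  counts <- .assayOrMatrix(sce, "counts")
  if (ncol(counts) == 0 || nrow(counts) == 0) stop("empty count matrix")
  sf <- switch(method,
    libsize = {
      ls <- colSums(counts)
      if (any(ls == 0)) {
        stop("zero-count cell(s): ",
             paste(colnames(counts)[ls == 0], collapse = ", "))
      }
      ls
    },
    median_ratio = {
      logGeo <- rowMeans(log(counts))
      use <- is.finite(logGeo)
      if (!any(use)) {
        stop("median_ratio failed: no gene is expressed in every cell")
      }
      ratios <- counts[use, , drop = FALSE] / exp(logGeo[use])
      f <- apply(ratios, 2, stats::median)
      if (any(f <= 0)) {
        stop("median_ratio produced non-positive size factor(s): ",
             paste(colnames(counts)[f <= 0], collapse = ", "))
      }
      f
    },
    external = {
      if (is.null(sizeFactors)) stop("method 'external' needs 'sizeFactors'")
      if (length(sizeFactors) != ncol(counts)) {
        stop("'sizeFactors' must have one entry per cell")
      }
      if (any(sizeFactors <= 0)) stop("size factors must be positive")
      as.numeric(sizeFactors)
    })
  sf <- sf / mean(sf)
  norm <- sweep(counts, 2, sf, "/")
  SummarizedExperiment::assay(sce, "normcounts") <- norm
  SummarizedExperiment::colData(sce)$sizeFactor <- sf
  metadata(sce)$normalization <- list(method = method)
  sce
}

#' Filter low-abundance genes
#'
#' Drops genes whose mean normalized expression lies at or below the given
#' percentile of per-gene means (nearest-rank percentile, determinate under
#' ties); a percentile of 0 retains every gene. Gene order is preserved.
#'
#' @param x a SingleCellExperiment with a \code{"normcounts"} assay, or a
#'   normalized genes-by-cells matrix.
#' @param percentile percentile of per-gene mean expression below which
#'   genes are discarded.
#' @return character vector of retained gene ids, in input order, with the
#'   threshold as attribute \code{"threshold"}.
#' @export
filterLowAbundanceGenes <- function(x, percentile = 70) {
  norm <- .assayOrMatrix(x, "normcounts")
  means <- rowMeans(norm)
  if (percentile <= 0) {
    keep <- rep(TRUE, length(means))
    thr <- -Inf
  } else {
    thr <- .nearestRankPercentile(means, percentile)
    keep <- means > thr
  }
  structure(rownames(norm)[keep], threshold = thr)
}

#' Second-pass cell filter on the retained genes
#'
#' Over the retained (high-abundance) genes only, removes cells whose
#' normalized library size falls below the configured cutoff (an absolute
#' value, or \code{median - 2 * MAD} when \code{minNormLibsize = "auto"})
#' or whose fraction of zero-count genes exceeds \code{maxZeroFraction}.
#'
#' @param sce a SingleCellExperiment with \code{"counts"} and
#'   \code{"normcounts"} assays.
#' @param genes character vector of retained gene ids (from
#'   [filterLowAbundanceGenes()]).
#' @param config a [qcConfig()].
#' @return character vector of retained cell ids with a \code{"report"}
#'   attribute (thresholds and per-cell removal reasons).
#' @export
filterCellsExpression <- function(sce, genes, config = qcConfig()) {
  if (!length(genes)) stop("'genes' must be non-empty")
  norm <- .assayOrMatrix(sce, "normcounts")[genes, , drop = FALSE]
  counts <- .assayOrMatrix(sce, "counts")[genes, , drop = FALSE]
  normLib <- colSums(norm)
  if (identical(config$minNormLibsize, "auto")) {
    thr <- stats::median(normLib) - 2 * stats::mad(normLib)
  } else {
    thr <- config$minNormLibsize
  }
  zeroFrac <- colMeans(counts == 0)
  lowLib <- normLib < thr
  highZero <- zeroFrac > config$maxZeroFraction
  drop <- lowLib | highZero
  if (all(drop)) stop("empty after QC: all cells removed by expression filter")
  report <- list(nInput = ncol(norm), nKept = sum(!drop),
                 nRemoved = sum(drop), libsizeThreshold = thr,
                 maxZeroFraction = config$maxZeroFraction,
                 removed = data.frame(cell = colnames(norm)[drop],
                                      lowNormLibsize = lowLib[drop],
                                      highZeroFraction = highZero[drop],
                                      row.names = NULL))
  structure(colnames(norm)[!drop], report = report)
}

#' Run the full QC and normalization pipeline
#'
#' Applies, in order: MAD-based cell QC ([filterCellsQC()]), size-factor
#' normalization ([normalizeCounts()]), low-abundance gene filtering
#' ([filterLowAbundanceGenes()]) and the second-pass cell filter
#' ([filterCellsExpression()]). Gene order is never changed, so the
#' genomic ordering needed by the sliding window is preserved.
#'
#' @inheritParams filterCellsQC
#' @inheritParams normalizeCounts
#' @return the filtered, normalized SingleCellExperiment; the individual
#'   filter reports live in \code{metadata()}.
#' @export
runQC <- function(sce, config = qcConfig(),
                  method = c("libsize", "median_ratio", "external"),
                  sizeFactors = NULL) {
  sce <- filterCellsQC(sce, config)
  if (!is.null(sizeFactors)) {
    sizeFactors <- sizeFactors[colnames(sce)]
  }
  sce <- normalizeCounts(sce, method = method, sizeFactors = sizeFactors)
  genes <- filterLowAbundanceGenes(sce, config$lowAbundancePercentile)
  cells <- filterCellsExpression(sce, genes, config)
  out <- sce[genes, cells]
  metadata(out)$geneFilter <- list(nInput = nrow(sce), nKept = length(genes),
                                   threshold = attr(genes, "threshold"))
  metadata(out)$expressionCellFilter <- attr(cells, "report")
  out
}
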