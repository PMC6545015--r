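# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream untouched so that wrapper
# functions can seed once and call sub-generators sequentially.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  expr
}

# Nearest-rank percentile: the smallest order statistic whose rank is
# >= ceiling(p/100 * n). Determinate under ties.
.nearestRankPercentile <- function(x, p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 100)
  xs <- sort(x)
  xs[max(1L, ceiling(p / 100 * length(xs)))]
}

# Pull a named assay out of a SummarizedExperiment-like object, or pass a
# plain matrix through.
.assayOrMatrix <- function(x, assayName) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!assayName %in% SummarizedExperiment::assayNames(x)) {
      stop("assay '", assayName, "' not found; run the upstream step first",
           call. = FALSE)
    }
    as.matrix(SummarizedExperiment::assay(x, assayName))
  } else if (is.matrix(x)) {
    x
  } else {
    as.matrix(x)
  }
}

.checkLabels <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("'labels' must have one entry per cell", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("reference", "test"))
  if (length(bad)) {
    stop("cell labels must be 'reference' or 'test'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  labels
}
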