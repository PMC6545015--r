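#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData rowRanges
#' @importFrom stats median quantile
NULL

#' Diploid reference expression profile
#'
#' Per-gene geometric mean of normalized expression (plus a pseudocount)
#' across the reference (diploid) cells. Relative expression of every cell
#' is computed against this profile on the log2 scale.
#'
#' @slot values named numeric vector, one strictly positive value per gene.
#' @slot pseudocount the pseudocount added before taking logs; recorded so
#'   the same offset is used when computing log ratios downstream.
#'
#' @seealso [buildReferenceProfile()], [relativeExpression()]
#' @exportClass ReferenceProfile
setClass("ReferenceProfile",
  slots = c(values = "numeric", pseudocount = "numeric"))

setValidity("ReferenceProfile", function(object) {
  msg <- NULL
  if (is.null(names(object@values)) || anyDuplicated(names(object@values))) {
    msg <- c(msg, "'values' must be uniquely named by gene id")
  }
  if (any(!is.finite(object@values)) || any(object@values <= 0)) {
    msg <- c(msg, "'values' must be strictly positive and finite")
  }
  if (length(object@pseudocount) != 1L || object@pseudocount < 0) {
    msg <- c(msg, "'pseudocount' must be a single non-negative number")
  }
  if (is.null(msg)) TRUE else msg
})

#' Estimated copy number experiment
#'
#' A \linkS4class{RangedSummarizedExperiment} holding, in genomic order, the
#' median-centered log2 relative expression (assay \code{"relexpr"}) and the
#' sliding-window estimated copy number (assay \code{"ecn"}, log2 scale,
#' 0 = diploid) for each gene and cell. The window radius and the
#' zero-forcing threshold used are stored in \code{metadata()}.
#'
#' The class guarantees the zero-forcing invariant: no ECN entry has a
#' magnitude strictly between 0 and the recorded threshold.
#'
#' @seealso [estimateECN()], [cinIndex()], [callChromosomeEvents()]
#' @exportClass EcnExperiment
setClass("EcnExperiment", contains = "RangedSummarizedExperiment")

setValidity("EcnExperiment", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("relexpr", "ecn") %in% an)) {
    msg <- c(msg, "assays 'relexpr' and 'ecn' are required")
  }
  md <- metadata(object)
  if (!is.numeric(md$windowRadius) || !is.numeric(md$zeroThreshold)) {
    msg <- c(msg, "metadata must record 'windowRadius' and 'zeroThreshold'")
  } else if ("ecn" %in% an) {
    e <- abs(SummarizedExperiment::assay(object, "ecn"))
    if (any(e > 0 & e < md$zeroThreshold)) {
      msg <- c(msg, "zero-forcing violated: |ECN| values in (0, threshold)")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Copy-number-independent gene signature
#'
#' Binary weight profiles: genes up-regulated independently of copy number
#' carry weight 1 in \code{wPlus}, down-regulated genes carry weight 1 in
#' \code{wMinus}, all other genes are implicitly 0. The two supports are
#' disjoint by construction.
#'
#' @slot wPlus character vector of up-regulated signature gene ids.
#' @slot wMinus character vector of down-regulated signature gene ids.
#'
#' @seealso [buildWeightProfiles()], [scoreSamples()]
#' @exportClass CiSignature
setClass("CiSignature", slots = c(wPlus = "character", wMinus = "character"))

setValidity("CiSignature", function(object) {
  msg <- NULL
  if (length(intersect(object@wPlus, object@wMinus))) {
    msg <- c(msg, "a gene cannot be in both wPlus and wMinus")
  }
  if (anyDuplicated(object@wPlus) || anyDuplicated(object@wMinus)) {
    msg <- c(msg, "duplicate gene ids in a weight profile")
  }
  if (length(object@wPlus) + length(object@wMinus) == 0L) {
    msg <- c(msg, "signature is empty")
  }
  if (is.null(msg)) TRUE else msg
})
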