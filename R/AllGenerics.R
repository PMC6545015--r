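#' @rdname ReferenceProfile-class
#' @param object,x a \linkS4class{ReferenceProfile}, \linkS4class{EcnExperiment}
#'   or \linkS4class{CiSignature} as appropriate.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname ReferenceProfile-class
#' @export
setGeneric("pseudocount", function(x) standardGeneric("pseudocount"))

#' @rdname EcnExperiment-class
#' @export
setGeneric("ecnMatrix", function(x) standardGeneric("ecnMatrix"))

#' @rdname EcnExperiment-class
#' @export
setGeneric("relExpr", function(x) standardGeneric("relExpr"))

#' @rdname EcnExperiment-class
#' @export
setGeneric("windowRadius", function(x) standardGeneric("windowRadius"))

#' @rdname EcnExperiment-class
#' @export
setGeneric("zeroThreshold", function(x) standardGeneric("zeroThreshold"))

#' Per-cell chromosomal instability index
#'
#' The chromosomal instability index of a cell is the mean absolute
#' estimated copy number over all genes used for copy-number estimation:
#' \eqn{CIN_k = \sum_i |ECN_k(i)| / n}. It is 0 exactly when every ECN entry
#' of the cell is 0 (a diploid expression profile), and grows with both the
#' number and the magnitude of inferred copy-number alterations.
#'
#' @param x an \linkS4class{EcnExperiment} or a genes-by-cells ECN matrix.
#' @return named numeric vector, one non-negative index per cell.
#' @examples
#' ecn <- rbind(c(1, 0), c(0, 0), c(-1, 0), c(0, 0))
#' colnames(ecn) <- c("cin_cell", "diploid_cell")
#' cinIndex(ecn)  # 0.5 and 0
#' @export
setGeneric("cinIndex", function(x) standardGeneric("cinIndex"))

#' @rdname CiSignature-class
#' @export
setGeneric("wPlus", function(x) standardGeneric("wPlus"))

#' @rdname CiSignature-class
#' @export
setGeneric("wMinus", function(x) standardGeneric("wMinus"))

#' @rdname ReferenceProfile-class
#' @export
setMethod("profileValues", "ReferenceProfile", function(x) x@values)

#' @rdname ReferenceProfile-class
#' @export
setMethod("pseudocount", "ReferenceProfile", function(x) x@pseudocount)

#' @rdname ReferenceProfile-class
#' @export
setMethod("show", "ReferenceProfile", function(object) {
  cat("ReferenceProfile with", length(object@values), "genes",
      "(pseudocount", object@pseudocount, ")\n")
  v <- object@values
  cat("  geometric-mean expression range:",
      format(min(v), digits = 4), "-", format(max(v), digits = 4), "\n")
})

#' @rdname EcnExperiment-class
#' @export
setMethod("ecnMatrix", "EcnExperiment", function(x) {
  SummarizedExperiment::assay(x, "ecn")
})

#' @rdname EcnExperiment-class
#' @export
setMethod("relExpr", "EcnExperiment", function(x) {
  SummarizedExperiment::assay(x, "relexpr")
})

#' @rdname EcnExperiment-class
#' @export
setMethod("windowRadius", "EcnExperiment", function(x) {
  metadata(x)$windowRadius
})

#' @rdname EcnExperiment-class
#' @export
setMethod("zeroThreshold", "EcnExperiment", function(x) {
  metadata(x)$zeroThreshold
})

#' @rdname EcnExperiment-class
#' @export
setMethod("show", "EcnExperiment", function(object) {
  methods::callNextMethod()
  cat("windowRadius:", metadata(object)$windowRadius,
      " zeroThreshold:", metadata(object)$zeroThreshold, "\n")
  nz <- mean(SummarizedExperiment::assay(object, "ecn") != 0)
  cat(sprintf("non-zero ECN entries: %.1f%%\n", 100 * nz))
})

#' @rdname CiSignature-class
#' @export
setMethod("wPlus", "CiSignature", function(x) x@wPlus)

#' @rdname CiSignature-class
#' @export
setMethod("wMinus", "CiSignature", function(x) x@wMinus)

#' @rdname CiSignature-class
#' @export
setMethod("show", "CiSignature", function(object) {
  cat("CiSignature:", length(object@wPlus), "up-regulated,",
      length(object@wMinus), "down-regulated genes\n")
})
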