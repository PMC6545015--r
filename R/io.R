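#' Assemble a count experiment from matrix, annotation and labels
#'
#' @param counts non-negative integer genes-by-cells matrix with unique
#'   dimnames.
#' @param annotation named GRanges covering all genes in \code{counts}.
#' @param labels per-cell labels (\code{"reference"} / \code{"test"}).
#' @return a \link[SingleCellExperiment]{SingleCellExperiment}.
#' @export
makeCountExperiment <- function(counts, annotation, labels) {
  counts <- as.matrix(counts)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate gene or cell ids")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  miss <- setdiff(rownames(counts), names(annotation))
  if (length(miss)) stop("genes without annotation: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  labels <- .checkLabels(labels, ncol(counts))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowRanges = annotation[rownames(counts)],
    colData = S4Vectors::DataFrame(label = labels,
                                   row.names = colnames(counts)))
}

#' Write / read a count matrix as a MatrixMarket triplet
#'
#' CellRanger-style layout: \code{matrix.mtx}, \code{genes.tsv} (gene id,
#' chromosome, start, mito flag) and \code{barcodes.tsv} (cell id, label).
#'
#' @param sce a SingleCellExperiment with a \code{"counts"} assay and
#'   GRanges rowRanges.
#' @param dir output (input) directory.
#' @return \code{writeCountsMTX}: the directory, invisibly;
#'   \code{readCountsMTX}: a SingleCellExperiment.
#' @export
writeCountsMTX <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- .assayOrMatrix(sce, "counts")
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  rr <- SummarizedExperiment::rowRanges(sce)
  genes <- data.frame(
    gene = rownames(sce),
    chromosome = as.character(GenomicRanges::seqnames(rr)),
    start = GenomicRanges::start(rr),
    mito = if (!is.null(rr$mito)) rr$mito else FALSE)
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  barcodes <- data.frame(cell = colnames(sce),
                         label = SummarizedExperiment::colData(sce)$label)
  utils::write.table(barcodes, file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCountsMTX
#' @export
readCountsMTX <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(file.path(dir, "barcodes.tsv"),
                                stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes$gene, barcodes$cell)
  ann <- GenomicRanges::GRanges(
    seqnames = factor(genes$chromosome, levels = unique(genes$chromosome)),
    ranges = IRanges::IRanges(start = genes$start, width = 1L),
    mito = if ("mito" %in% names(genes)) genes$mito else FALSE)
  names(ann) <- genes$gene
  makeCountExperiment(counts, ann, barcodes$label)
}

#' Read a BED-like gene annotation TSV
#'
#' Expects columns \code{gene}, \code{chromosome}, \code{start} and
#' optionally \code{mito}.
#'
#' @param file path to the TSV.
#' @return a named, sorted GRanges.
#' @export
readGeneAnnotation <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "start")
  if (!all(need %in% names(df))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[order(match(df$chromosome, unique(df$chromosome)), df$start), ]
  ann <- GenomicRanges::GRanges(
    seqnames = factor(df$chromosome, levels = unique(df$chromosome)),
    ranges = IRanges::IRanges(start = df$start, width = 1L),
    mito = if ("mito" %in% names(df)) df$mito else FALSE)
  names(ann) <- df$gene
  ann
}

#' Write / read weight profiles as JSON
#'
#' Stored as a gene id to weight map (+1 for w+ genes, -1 for w- genes).
#'
#' @param weights a \linkS4class{CiSignature}.
#' @param file path to the JSON file.
#' @return \code{readWeightProfiles}: a \linkS4class{CiSignature}.
#' @export
writeWeightProfiles <- function(weights, file) {
  stopifnot(methods::is(weights, "CiSignature"))
  w <- c(stats::setNames(rep(1L, length(wPlus(weights))), wPlus(weights)),
         stats::setNames(rep(-1L, length(wMinus(weights))), wMinus(weights)))
  jsonlite::write_json(as.list(w), file, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeWeightProfiles
#' @export
readWeightProfiles <- function(file) {
  w <- unlist(jsonlite::read_json(file))
  methods::new("CiSignature",
               wPlus = names(w)[w > 0], wMinus = names(w)[w < 0])
}

#' Write a genes-by-cells matrix (e.g. ECN or normalized expression) as TSV
#'
#' @param mat numeric matrix with dimnames.
#' @param file output path.
#' @export
writeMatrixTSV <- function(mat, file) {
  utils::write.table(data.frame(gene = rownames(mat), mat,
                                check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
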