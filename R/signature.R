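#' Build binary weight profiles from the gene classification
#'
#' Genes classified copy-number independent and up-regulated get weight 1
#' in the w+ profile; copy-number independent down-regulated genes get
#' weight 1 in w-; every other gene is 0 in both. The support of the
#' signature is exactly the copy-number-independent gene set.
#'
#' @param classification output of [classifyGenes()].
#' @return a \linkS4class{CiSignature}.
#' @export
buildWeightProfiles <- function(classification) {
  ci <- classification[classification$class == "cn_independent", ]
  if (!nrow(ci)) stop("empty copy-number-independent set: no signature")
  methods::new("CiSignature",
               wPlus = ci$gene[ci$direction == "up"],
               wMinus = ci$gene[ci$direction == "down"])
}

# Signed running-sum enrichment statistic for one ranked gene list: the
# maximum difference between the cumulative fraction of signature genes and
# the cumulative fraction of non-signature genes from the top of the
# ranking.
.rankES <- function(ranking, sig) {
  inSig <- ranking %in% sig
  nSig <- sum(inSig)
  nBg <- length(ranking) - nSig
  if (nSig == 0 || nBg == 0) return(0)
  max(cumsum(inSig) / nSig - cumsum(!inSig) / nBg)
}

#' Score bulk samples with the CI signature
#'
#' Two scoring methods over the binary weight profiles:
#' \describe{
#'   \item{meanz (default)}{z-score each gene across samples, then
#'     \code{score = mean(z over w+ genes) - mean(z over w- genes)}.
#'     Deterministic, shift-invariant per gene, and antisymmetric under
#'     swapping the two profiles.}
#'   \item{rank_es}{per sample, rank genes by expression (descending) and
#'     take the running-sum enrichment statistic — the maximum lead of the
#'     cumulative fraction of signature genes over the cumulative fraction
#'     of background genes — separately for w+ and w-;
#'     \code{score = ES(w+) - ES(w-)}. A rank-based analogue of weighted
#'     signature-projection methods.}
#' }
#' Signature genes missing from the expression matrix are dropped with a
#' warning; if an entire non-empty profile is absent the scoring errors.
#'
#' @param expression genes-by-samples numeric matrix (bulk cohort).
#' @param weights a \linkS4class{CiSignature}.
#' @param method \code{"meanz"} or \code{"rank_es"}.
#' @return data.frame with columns \code{sample} and \code{score}; the
#'   method and dropped genes are recorded as attributes.
#' @export
scoreSamples <- function(expression, weights, method = c("meanz", "rank_es")) {
  method <- match.arg(method)
  stopifnot(methods::is(weights, "CiSignature"))
  if (ncol(expression) < 4) stop("need at least 4 samples")
  up <- wPlus(weights)
  dn <- wMinus(weights)
  upIn <- intersect(up, rownames(expression))
  dnIn <- intersect(dn, rownames(expression))
  if (length(up) && !length(upIn)) {
    stop("no w+ signature gene present in the expression matrix")
  }
  if (length(dn) && !length(dnIn)) {
    stop("no w- signature gene present in the expression matrix")
  }
  dropped <- setdiff(c(up, dn), c(upIn, dnIn))
  if (length(dropped)) {
    warning("signature genes absent from the matrix dropped: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) sprintf(" ... (%d total)",
                                              length(dropped)))
  }
  if (method == "meanz") {
    sds <- apply(expression, 1, stats::sd)
    z <- (expression - rowMeans(expression)) / ifelse(sds == 0, 1, sds)
    z[sds == 0, ] <- 0
    plus <- if (length(upIn)) colMeans(z[upIn, , drop = FALSE]) else 0
    minus <- if (length(dnIn)) colMeans(z[dnIn, , drop = FALSE]) else 0
    score <- plus - minus
  } else {
    score <- vapply(seq_len(ncol(expression)), function(s) {
      ranking <- rownames(expression)[
        order(expression[, s], rownames(expression), decreasing = TRUE)]
      esUp <- if (length(upIn)) .rankES(ranking, upIn) else 0
      esDn <- if (length(dnIn)) .rankES(ranking, dnIn) else 0
      esUp - esDn
    }, numeric(1))
  }
  out <- data.frame(sample = colnames(expression), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "droppedGenes") <- dropped
  out
}

#' Dichotomize samples into CI-Hi and CI-Lo at the median score
#'
#' Samples scoring strictly above the cohort median go to CI-Hi, all
#' others (including scores exactly at the median) to CI-Lo — a
#' deterministic tie rule that is conservative for the Hi group. With
#' distinct scores the two groups differ in size by at most 1.
#'
#' @param scores output of [scoreSamples()].
#' @return the table with an added \code{group} factor (\code{CI-Lo},
#'   \code{CI-Hi}); degenerate scoring (all scores equal) triggers a
#'   warning.
#' @export
dichotomize <- function(scores) {
  if (nrow(scores) < 4) stop("need at least 4 samples")
  med <- stats::median(scores$score)
  grp <- ifelse(scores$score > med, "CI-Hi", "CI-Lo")
  if (length(unique(scores$score)) == 1L) {
    warning("degenerate dichotomization: all scores equal; ",
            "all samples assigned CI-Lo")
  }
  scores$rank <- rank(scores$score, ties.method = "average")
  scores$group <- factor(grp, levels = c("CI-Lo", "CI-Hi"))
  attr(scores, "groupSizes") <- table(scores$group)
  scores
}
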