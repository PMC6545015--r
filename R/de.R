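#' Unadjusted differential expression between cell populations
#'
#' Per gene: a two-sided Mann-Whitney U test (exact when both groups have
#' at most \code{exactMax} cells and the data are tie-free, otherwise the
#' tie-corrected normal approximation), a Welch t test, the log2 fold
#' change of group means (with pseudocount), and the mean expression over
#' all cells. Mann-Whitney p-values are Bonferroni-corrected over all
#' tested genes; a gene is significant when the corrected p-value is below
#' \code{alpha}.
#'
#' @param x a SingleCellExperiment with a \code{"normcounts"} assay, or a
#'   normalized genes-by-cells matrix.
#' @param labels per-cell labels, \code{"reference"} / \code{"test"};
#'   defaults to the colData \code{label} column.
#' @param pseudocount added to group means before the log2 fold change.
#' @param alpha significance level on the Bonferroni-corrected p.
#' @param exactMax maximum group size for the exact Mann-Whitney test.
#' @return data.frame with one row per gene: \code{gene}, \code{t_score},
#'   \code{t_pvalue}, \code{mw_pvalue}, \code{log2_fc} (test vs reference),
#'   \code{mean_expression}, \code{mw_p_adjust}, \code{significant}.
#' @export
differentialExpression <- function(x, labels = NULL, pseudocount = 1,
                                   alpha = 0.05, exactMax = 20) {
  norm <- .assayOrMatrix(x, "normcounts")
  if (is.null(labels) && methods::is(x, "SummarizedExperiment")) {
    labels <- SummarizedExperiment::colData(x)$label
  }
  labels <- .checkLabels(labels, ncol(norm))
  isTest <- labels == "test"
  if (sum(isTest) < 2 || sum(!isTest) < 2) {
    stop("each group needs at least 2 cells")
  }
  exact <- sum(isTest) <= exactMax && sum(!isTest) <= exactMax
  res <- vapply(seq_len(nrow(norm)), function(i) {
    a <- norm[i, isTest]
    b <- norm[i, !isTest]
    mw <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact)$p.value)
    if (is.nan(mw)) mw <- 1  # all values tied across both groups
    tt <- tryCatch(stats::t.test(a, b),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    c(t_score = unname(tt$statistic), t_pvalue = tt$p.value,
      mw_pvalue = mw,
      log2_fc = log2((mean(a) + pseudocount) / (mean(b) + pseudocount)),
      mean_expression = mean(c(a, b)))
  }, numeric(5))
  out <- data.frame(gene = rownames(norm), t(res), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$mw_p_adjust <- stats::p.adjust(out$mw_pvalue, method = "bonferroni")
  out$significant <- out$mw_p_adjust < alpha
  out
}

#' Impute ECN for genes lacking window estimates
#'
#' Genes already present in the ECN matrix pass through unchanged. A gene
#' without an estimate takes, per cell, the average of its nearest flanking
#' genes with ECN on the same chromosome (the closest gene on each side by
#' coordinate); a gene upstream of the first or downstream of the last ECN
#' gene takes the one-sided nearest value. Genes on chromosomes carrying no
#' ECN genes at all cannot be imputed and are excluded (listed in the
#' \code{"missing"} attribute).
#'
#' @param ecn an \linkS4class{EcnExperiment}.
#' @param annotation named GRanges covering (at least) the target genes.
#' @param targetGenes character vector of gene ids to return.
#' @return genes-by-cells matrix of ECN for the imputable target genes,
#'   with attributes \code{"imputed"} (logical per returned gene) and
#'   \code{"missing"} (excluded gene ids).
#' @export
imputeGeneEcn <- function(ecn, annotation, targetGenes) {
  stopifnot(methods::is(ecn, "EcnExperiment"))
  e <- ecnMatrix(ecn)
  bad <- setdiff(targetGenes, names(annotation))
  if (length(bad)) stop("target genes without annotation: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  chromAll <- as.character(GenomicRanges::seqnames(annotation))
  startAll <- GenomicRanges::start(annotation)
  names(chromAll) <- names(startAll) <- names(annotation)
  known <- intersect(rownames(e), names(annotation))
  out <- matrix(NA_real_, length(targetGenes), ncol(e),
                dimnames = list(targetGenes, colnames(e)))
  imputed <- stats::setNames(rep(FALSE, length(targetGenes)), targetGenes)
  missing <- character()
  for (g in targetGenes) {
    if (g %in% rownames(e)) {
      out[g, ] <- e[g, ]
      next
    }
    sameChrom <- known[chromAll[known] == chromAll[g]]
    if (!length(sameChrom)) {
      missing <- c(missing, g)
      next
    }
    pos <- startAll[sameChrom]
    left <- sameChrom[pos <= startAll[g]]
    right <- sameChrom[pos >= startAll[g]]
    flanks <- c(
      if (length(left)) left[which.max(pos[left])],
      if (length(right)) right[which.min(pos[right])])
    out[g, ] <- colMeans(e[flanks, , drop = FALSE])
    imputed[g] <- TRUE
  }
  if (length(missing)) {
    warning(length(missing), " gene(s) on chromosomes without ECN excluded")
    out <- out[setdiff(targetGenes, missing), , drop = FALSE]
    imputed <- imputed[rownames(out)]
  }
  structure(out, imputed = imputed, missing = missing)
}

# Ridge-penalized logistic regression by Newton iterations; used as the
# fallback when the unpenalized per-gene fit separates or fails to
# converge. The intercept is not penalized. Wald SEs come from the
# penalized information matrix.
.ridgeLogistic <- function(Xm, y, lambda, maxit = 200, tol = 1e-9) {
  p <- ncol(Xm)
  pen <- diag(c(0, rep(2 * lambda, p - 1)), nrow = p)
  beta <- numeric(p)
  H <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(Xm %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xm, Xm * w) + pen
    g <- crossprod(Xm, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, p))
  list(coef = drop(beta), se = se)
}

#' Copy-number-adjusted differential expression
#'
#' Per gene, fits a logistic regression of the cell label (1 = test, 0 =
#' reference) on the gene's expression and its per-cell estimated copy
#' number:
#' \deqn{\mathrm{logit}(Y) = \beta_0 + \beta_1 \cdot exp + \beta_2 \cdot CNV}
#' The expression predictor is log2(normalized + 1), standardized per gene
#' across cells; the CNV covariate is the per-cell ECN of the gene
#' (estimated or imputed). A significant \eqn{\beta_1} means expression
#' still separates the populations after accounting for copy number — the
#' copy-number-independent component of differential expression. Wald
#' p-values on \eqn{\beta_1} are Bonferroni-corrected over the genes
#' tested. Fits showing separation or non-convergence are refit with an L2
#' penalty of \code{1/(2 * nCells)} and flagged. The per-gene Pearson and
#' Spearman correlations between normalized expression and ECN across cells
#' are recorded.
#'
#' @inheritParams differentialExpression
#' @param ecnFull genes-by-cells ECN matrix covering the genes to test (see
#'   [imputeGeneEcn()]); cells must match \code{x}.
#' @param genes genes to fit; default all genes present in both \code{x}
#'   and \code{ecnFull}.
#' @param test \code{"wald"} (default) or \code{"lrt"} for the
#'   \eqn{\beta_1} p-value.
#' @return data.frame with one row per tested gene: \code{gene},
#'   \code{beta0}, \code{beta1}, \code{beta2}, \code{beta1_pvalue},
#'   \code{beta1_p_adjust}, \code{pearson}, \code{spearman},
#'   \code{separated}, \code{ecn_imputed} (when known), plus skipped
#'   constant-expression genes flagged via NA coefficients.
#' @export
cnAdjustedDE <- function(x, labels = NULL, ecnFull, genes = NULL,
                         test = c("wald", "lrt")) {
  test <- match.arg(test)
  norm <- .assayOrMatrix(x, "normcounts")
  if (is.null(labels) && methods::is(x, "SummarizedExperiment")) {
    labels <- SummarizedExperiment::colData(x)$label
  }
  labels <- .checkLabels(labels, ncol(norm))
  stopifnot(is.matrix(ecnFull))
  cells <- colnames(norm)
  if (!all(cells %in% colnames(ecnFull))) {
    stop("ecnFull does not cover all cells")
  }
  ecnFull <- ecnFull[, cells, drop = FALSE]
  if (is.null(genes)) {
    genes <- intersect(rownames(norm), rownames(ecnFull))
  } else {
    noEcn <- setdiff(genes, rownames(ecnFull))
    if (length(noEcn)) {
      message(length(noEcn), " gene(s) without ECN excluded from adjustment")
      genes <- intersect(genes, rownames(ecnFull))
    }
    bad <- setdiff(genes, rownames(norm))
    if (length(bad)) stop("genes not in the expression matrix: ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  y <- as.numeric(labels == "test")
  n <- length(y)
  lambda <- 1 / (2 * n)
  imputedFlag <- attr(ecnFull, "imputed")
  rows <- lapply(genes, function(g) {
    expr <- norm[g, ]
    le <- log2(expr + 1)
    if (stats::sd(le) == 0) {
      return(data.frame(gene = g, beta0 = NA_real_, beta1 = NA_real_,
                        beta2 = NA_real_, beta1_pvalue = NA_real_,
                        pearson = NA_real_, spearman = NA_real_,
                        separated = FALSE, constant = TRUE))
    }
    z <- as.numeric(scale(le))
    e <- ecnFull[g, ]
    ecnConstant <- stats::sd(e) == 0
    df <- data.frame(y = y, z = z, e = e)
    form <- if (ecnConstant) y ~ z else y ~ z + e
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(form, family = stats::binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    if (!sep && "z" %in% rownames(co)) {
      sep <- abs(co["z", "Estimate"]) > 15 || co["z", "Std. Error"] > 100
    }
    if (sep) {
      # Wald on a weakly penalized fit is uninformative under separation
      # (the penalized information is dominated by the penalty), so the
      # expression term is tested by a penalized likelihood ratio instead.
      Xm <- cbind(1, z, if (!ecnConstant) e)
      rf <- .ridgeLogistic(Xm, y, lambda)
      rf0 <- .ridgeLogistic(Xm[, -2, drop = FALSE], y, lambda)
      beta0 <- rf$coef[1]; beta1 <- rf$coef[2]
      beta2 <- if (ecnConstant) NA_real_ else rf$coef[3]
      dev <- function(b, M) {
        eta <- drop(M %*% b)
        -2 * sum(y * eta - log1p(exp(eta)))
      }
      lr <- dev(rf0$coef, Xm[, -2, drop = FALSE]) - dev(rf$coef, Xm)
      p1 <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    } else {
      beta0 <- co["(Intercept)", "Estimate"]
      beta1 <- co["z", "Estimate"]
      beta2 <- if (!ecnConstant && "e" %in% rownames(co)) {
        co["e", "Estimate"]
      } else NA_real_
      if (test == "lrt") {
        fit0 <- stats::glm(if (ecnConstant) y ~ 1 else y ~ e,
                           family = stats::binomial(), data = df)
        p1 <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                            lower.tail = FALSE)
      } else {
        p1 <- co["z", "Pr(>|z|)"]
      }
    }
    data.frame(gene = g, beta0 = beta0, beta1 = beta1, beta2 = beta2,
               beta1_pvalue = p1,
               pearson = if (ecnConstant) NA_real_ else
                 stats::cor(expr, e),
               spearman = if (ecnConstant) NA_real_ else
                 stats::cor(expr, e, method = "spearman"),
               separated = sep, constant = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$beta1_pvalue)
  out$beta1_p_adjust <- NA_real_
  out$beta1_p_adjust[tested] <- stats::p.adjust(out$beta1_pvalue[tested],
                                                method = "bonferroni")
  if (!is.null(imputedFlag)) {
    out$ecn_imputed <- unname(imputedFlag[out$gene])
  }
  row.names(out) <- NULL
  out
}

#' Classify genes as copy-number dependent or independent
#'
#' Within the unadjusted-significant gene set: genes whose adjusted
#' expression coefficient stays significant
#' (\code{beta1_p_adjust < alpha}) are copy-number independent — their
#' differential expression is not explained by copy number; genes that
#' lose significance after adjustment are copy-number dependent. Direction
#' (up/down in the test population) comes from the sign of \eqn{\beta_1}
#' (falling back on the unadjusted fold change when the adjusted fit was
#' skipped).
#'
#' @param de output of [differentialExpression()].
#' @param adj output of [cnAdjustedDE()].
#' @param alpha significance level (applies to both corrected p-values).
#' @return data.frame with \code{gene}, \code{class} (\code{not_de} /
#'   \code{cn_dependent} / \code{cn_independent}) and \code{direction}
#'   (\code{up} / \code{down}, NA for \code{not_de}).
#' @export
classifyGenes <- function(de, adj, alpha = 0.05) {
  m <- merge(de[, c("gene", "mw_p_adjust", "log2_fc")],
             adj[, c("gene", "beta1", "beta1_p_adjust")],
             by = "gene", all.x = TRUE, sort = FALSE)
  unadjSig <- m$mw_p_adjust < alpha
  adjSig <- !is.na(m$beta1_p_adjust) & m$beta1_p_adjust < alpha
  cls <- ifelse(!unadjSig, "not_de",
                ifelse(adjSig, "cn_independent", "cn_dependent"))
  dirSign <- ifelse(is.na(m$beta1), sign(m$log2_fc), sign(m$beta1))
  direction <- ifelse(cls == "not_de", NA_character_,
                      ifelse(dirSign >= 0, "up", "down"))
  data.frame(gene = m$gene,
             class = factor(cls, levels = c("not_de", "cn_dependent",
                                            "cn_independent")),
             direction = direction, stringsAsFactors = FALSE)
}
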