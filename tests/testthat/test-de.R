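test_that("differential expression finds nothing between identical groups", {
  set.seed(1)
  base <- matrix(rpois(50 * 10, 20), nrow = 50)
  counts <- cbind(base, base)
  labels <- rep(c("reference", "test"), each = 10)
  sce <- normalizeCounts(toySCE(counts, labels))
  de <- differentialExpression(sce)
  expect_false(any(de$significant))
  expect_true(all(de$mw_pvalue > 0.9))
  expect_equal(de$log2_fc, rep(0, 50))
})

test_that("a fully separated gene is significant with positive fold change", {
  set.seed(2)
  counts <- matrix(rpois(30 * 40, 20), nrow = 30)
  counts[1, ] <- c(rep(1L, 20), rep(10L, 20))
  labels <- rep(c("reference", "test"), each = 20)
  sce <- normalizeCounts(toySCE(counts, labels),
                         method = "external", sizeFactors = rep(1, 40))
  de <- differentialExpression(sce)
  expect_true(de$significant[de$gene == "g001"])
  expect_gt(de$log2_fc[de$gene == "g001"], 0)
})

test_that("Mann-Whitney p-values are location-invariant and Bonferroni monotone", {
  set.seed(3)
  counts <- matrix(rpois(20 * 30, 15), nrow = 20)
  labels <- rep(c("reference", "test"), each = 15)
  sce <- normalizeCounts(toySCE(counts, labels),
                         method = "external", sizeFactors = rep(1, 30))
  de <- differentialExpression(sce)
  shifted <- counts
  shifted[5, ] <- shifted[5, ] + 1000L
  de2 <- differentialExpression(
    normalizeCounts(toySCE(shifted, labels), method = "external",
                    sizeFactors = rep(1, 30)))
  expect_equal(de$mw_pvalue[5], de2$mw_pvalue[5])
  expect_true(all(de$mw_p_adjust >= de$mw_pvalue))
  expect_true(all(de$mw_p_adjust <= 1))

  expect_error(differentialExpression(
    normalizeCounts(toySCE(counts[, 1:3],
                           c("reference", "test", "test"))),
    labels = c("reference", "test", "test")), "at least 2")
})

test_that("null simulation keeps the pre-correction type-I error near alpha", {
  set.seed(4)
  nGenes <- 500
  counts <- matrix(rpois(nGenes * 60, 30), nrow = nGenes)
  labels <- rep(c("reference", "test"), each = 30)
  sce <- normalizeCounts(toySCE(counts, labels), method = "external",
                         sizeFactors = rep(1, 60))
  de <- differentialExpression(sce)
  typeI <- mean(de$mw_pvalue < 0.05)
  expect_lt(abs(typeI - 0.05), 3 * sqrt(0.05 * 0.95 / nGenes))
  expect_lte(sum(de$significant), 1)
})

test_that("ECN imputation averages the nearest flanking genes", {
  ann <- toyAnnotation(rep("chr1", 5), start = c(100, 200, 300, 400, 500))
  X <- matrix(c(0.8, 0.8, 0.8, 0.8), 4, 1,
              dimnames = list(names(ann)[c(1, 2, 4, 5)], "cell"))
  # give the 4 known genes distinct ECN by using radius 0, no threshold
  X[, 1] <- c(0.4, 0.4, 0.6, 0.9)
  ecn <- estimateECN(X, ann[c(1, 2, 4, 5)], windowRadius = 0,
                     zeroThreshold = 0)
  imp <- imputeGeneEcn(ecn, ann, names(ann))
  expect_equal(unname(imp["g003", "cell"]), 0.5)  # flanks 0.4 and 0.6
  expect_false(attr(imp, "imputed")[["g001"]])
  expect_true(attr(imp, "imputed")[["g003"]])

  # a gene upstream of all known genes takes the one-sided nearest value
  ann2 <- toyAnnotation(rep("chr1", 3), start = c(50, 100, 200),
                        ids = c("new", "k1", "k2"))
  X2 <- matrix(c(0.4, 0.9), 2, 1, dimnames = list(c("k1", "k2"), "cell"))
  ecn2 <- estimateECN(X2, ann2[c("k1", "k2")], windowRadius = 0,
                      zeroThreshold = 0)
  imp2 <- imputeGeneEcn(ecn2, ann2, c("new", "k1"))
  expect_equal(unname(imp2["new", "cell"]), 0.4)

  # genes on a chromosome without any ECN are flagged missing
  ann3 <- toyAnnotation(c("chr1", "chr2"), ids = c("k1", "lost"))
  X3 <- matrix(1, 1, 1, dimnames = list("k1", "cell"))
  expect_warning(
    ecn3 <- estimateECN(X3, ann3["k1"], windowRadius = 0, zeroThreshold = 0),
    "skipped")
  expect_warning(imp3 <- imputeGeneEcn(ecn3, ann3, c("k1", "lost")),
                 "excluded")
  expect_identical(attr(imp3, "missing"), "lost")
  expect_false("lost" %in% rownames(imp3))
})

test_that("held-out genes are imputed close to their windowed estimates", {
  sim <- recoverySim(nRef = 30, nTest = 30, seed = 77)
  ecn <- runEcnPipeline(sim$sce)
  set.seed(78)
  held <- sample(rownames(ecn), 50)
  # rebuild an EcnExperiment without the held-out genes
  ecnRed <- estimateECN(relExpr(ecn)[setdiff(rownames(ecn), held), ],
                        SummarizedExperiment::rowRanges(ecn)[
                          setdiff(rownames(ecn), held)])
  imp <- imputeGeneEcn(ecnRed, SummarizedExperiment::rowRanges(sim$sce), held)
  truthEcn <- ecnMatrix(ecn)[rownames(imp), ]
  expect_gt(stats::cor(as.numeric(imp), as.numeric(truthEcn)), 0.9)
})

test_that("an all-zero ECN column degenerates to the unadjusted logistic fit", {
  set.seed(5)
  counts <- matrix(rpois(10 * 40, 20), nrow = 10)
  counts[1, 21:40] <- rpois(20, 30)
  labels <- rep(c("reference", "test"), each = 20)
  sce <- normalizeCounts(toySCE(counts, labels), method = "external",
                         sizeFactors = rep(1, 40))
  ecnZero <- matrix(0, 10, 40, dimnames = dimnames(counts))
  dimnames(ecnZero) <- list(rownames(sce), colnames(sce))
  adj <- cnAdjustedDE(sce, ecnFull = ecnZero)
  norm <- SummarizedExperiment::assay(sce, "normcounts")
  z <- as.numeric(scale(log2(norm["g001", ] + 1)))
  ref <- summary(stats::glm((labels == "test") ~ z,
                            family = stats::binomial()))$coefficients
  got <- adj[adj$gene == "g001", ]
  expect_true(is.na(got$beta2))
  expect_lt(abs(got$beta1_pvalue - ref["z", "Pr(>|z|)"]) /
              ref["z", "Pr(>|z|)"], 0.1)
})

test_that("a buffered gene with a planted group effect keeps a signed beta1", {
  sim <- recoverySim(seed = 55)
  sce <- normalizeCounts(sim$sce)
  ecn <- runEcnPipeline(sim$sce)
  ecnFull <- imputeGeneEcn(ecn, SummarizedExperiment::rowRanges(sim$sce),
                           rownames(sce))
  genes <- c(sim$deUp[1:5], sim$deDn[1:5])
  adj <- cnAdjustedDE(sce, ecnFull = ecnFull, genes = genes)
  expect_true(all(adj$beta1[match(sim$deUp[1:5], adj$gene)] > 0))
  expect_true(all(adj$beta1[match(sim$deDn[1:5], adj$gene)] < 0))
  expect_true(all(adj$beta1_pvalue[!adj$constant] <= 1))
})

test_that("constant-expression genes are skipped with a flag", {
  counts <- matrix(rpois(5 * 20, 10), nrow = 5)
  counts[2, ] <- 7L
  labels <- rep(c("reference", "test"), each = 10)
  sce <- normalizeCounts(toySCE(counts, labels), method = "external",
                         sizeFactors = rep(1, 20))
  ecnFull <- matrix(0.3, 5, 20, dimnames = list(rownames(sce),
                                                colnames(sce)))
  adj <- cnAdjustedDE(sce, ecnFull = ecnFull)
  expect_true(adj$constant[adj$gene == "g002"])
  expect_true(is.na(adj$beta1[adj$gene == "g002"]))
})

test_that("classification splits the significant set into disjoint classes", {
  de <- data.frame(gene = paste0("g", 1:4),
                   mw_p_adjust = c(0.001, 0.001, 0.2, 0.001),
                   log2_fc = c(1, -1, 0.5, 2))
  adj <- data.frame(gene = paste0("g", 1:4),
                    beta1 = c(2, -2, 1, 0.1),
                    beta1_p_adjust = c(0.01, 0.001, 0.9, 0.6))
  cls <- classifyGenes(de, adj)
  expect_identical(as.character(cls$class),
                   c("cn_independent", "cn_independent", "not_de",
                     "cn_dependent"))
  expect_identical(cls$direction, c("up", "down", NA, "up"))

  # empty significant set: everything not_de
  de0 <- transform(de, mw_p_adjust = 1)
  cls0 <- classifyGenes(de0, adj)
  expect_true(all(cls0$class == "not_de"))
})
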