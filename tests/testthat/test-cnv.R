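test_that("reference profile is the pseudocounted geometric mean", {
  m <- rbind(g1 = c(4, 4, 4), g2 = c(1, 4, 16))
  colnames(m) <- c("a", "b", "c")
  p0 <- buildReferenceProfile(m, c("a", "b", "c"), pseudocount = 0)
  expect_equal(unname(profileValues(p0)["g1"]), 4)
  p1 <- buildReferenceProfile(m[, 1:2, drop = FALSE], c("a", "b"),
                              pseudocount = 0)
  expect_equal(unname(profileValues(p1)["g2"]), 2)
  m2 <- rbind(g1 = c(0, 8))
  colnames(m2) <- c("a", "b")
  p2 <- buildReferenceProfile(m2, c("a", "b"), pseudocount = 1)
  expect_equal(unname(profileValues(p2)["g1"]), 3)
  expect_error(buildReferenceProfile(m[, 1, drop = FALSE], "a"),
               "at least 2")
})

test_that("relative expression is a median-centered log2 ratio", {
  ref <- rbind(g1 = c(4, 4), g2 = c(8, 8), g3 = c(16, 16), g4 = c(32, 32))
  colnames(ref) <- c("r1", "r2")
  prof <- buildReferenceProfile(ref, c("r1", "r2"), pseudocount = 0)

  # a cell equal to the profile: X = 0 everywhere
  X <- relativeExpression(cbind(ref, same = c(4, 8, 16, 32)), prof)
  expect_equal(unname(X[, "same"]), rep(0, 4))

  # a cell at 2x the profile: the global shift is absorbed by centering
  X2 <- relativeExpression(cbind(ref, dbl = 2 * c(4, 8, 16, 32)), prof)
  expect_equal(unname(X2[, "dbl"]), rep(0, 4))

  # half the genes at 2x, half at 1x: +-0.5 after centering
  X3 <- relativeExpression(cbind(ref, mix = c(8, 16, 16, 32)), prof)
  expect_equal(sort(unique(round(X3[, "mix"], 10))), c(-0.5, 0.5))
  expect_equal(median(X3[, "mix"]), 0)

  bad <- rbind(other = c(1, 1))
  colnames(bad) <- c("r1", "r2")
  expect_error(relativeExpression(bad, prof), "missing")
})

test_that("sliding-window ECN matches hand-computed windows", {
  ann <- toyAnnotation(rep("chr1", 5))
  X <- matrix(c(0.9, 0.9, 0.3, 0.9, 0.9), ncol = 1,
              dimnames = list(names(ann), "cell"))
  ecn <- estimateECN(X, ann, windowRadius = 1, zeroThreshold = 0.5)
  expect_equal(unname(ecnMatrix(ecn)[, 1]), c(0.9, 0.7, 0.7, 0.7, 0.9))

  Xlow <- matrix(0.3, 5, 1, dimnames = list(names(ann), "cell"))
  ecnLow <- estimateECN(Xlow, ann, windowRadius = 1, zeroThreshold = 0.5)
  expect_true(all(ecnMatrix(ecnLow) == 0))

  # constant X = c with |c| above threshold survives everywhere
  Xc <- matrix(-0.8, 5, 1, dimnames = list(names(ann), "cell"))
  expect_equal(unname(ecnMatrix(estimateECN(Xc, ann, 2))[, 1]),
               rep(-0.8, 5))

  # X = 0 everywhere reads as diploid
  X0 <- matrix(0, 5, 1, dimnames = list(names(ann), "cell"))
  expect_true(all(ecnMatrix(estimateECN(X0, ann)) == 0))
})

test_that("windows never cross chromosome boundaries", {
  ann <- toyAnnotation(rep(c("chr1", "chr2"), each = 10))
  X <- matrix(rep(c(1, -1), each = 10), ncol = 3, nrow = 20,
              dimnames = list(names(ann), paste0("c", 1:3)))
  e <- ecnMatrix(estimateECN(X, ann, windowRadius = 5))
  expect_true(all(e[1:10, ] == 1))
  expect_true(all(e[11:20, ] == -1))
})

test_that("windowed ECN equals the brute-force neighbor loop", {
  set.seed(99)
  for (rep in 1:10) {
    chrom <- rep(paste0("chr", 1:3), times = c(25, 40, 15))
    ann <- toyAnnotation(chrom)
    X <- matrix(rnorm(80 * 6), 80, 6,
                dimnames = list(names(ann), paste0("c", 1:6)))
    radius <- sample(c(1, 3, 10, 60), 1)
    ecn <- estimateECN(X, ann, windowRadius = radius, zeroThreshold = 0)
    oracle <- bruteForceECN(X, chrom, radius)
    expect_lt(max(abs(ecnMatrix(ecn) - oracle)), 1e-12)
  }
})

test_that("estimateECN validates ordering and excludes mito genes", {
  ann <- toyAnnotation(c("chr1", "chr1", "chr1"), start = c(300, 100, 200))
  X <- matrix(0, 3, 2, dimnames = list(names(ann), c("a", "b")))
  expect_error(estimateECN(X, ann), "not sorted")

  ann2 <- toyAnnotation(c("chr1", "chr1", "MT"), mito = c(FALSE, FALSE, TRUE))
  X2 <- matrix(1, 3, 2, dimnames = list(names(ann2), c("a", "b")))
  ecn2 <- estimateECN(X2, ann2)
  expect_equal(nrow(ecn2), 2)
  expect_false("g003" %in% rownames(ecn2))
})

test_that("no ECN magnitude falls inside the dead zone", {
  set.seed(11)
  ann <- toyAnnotation(rep(c("chr1", "chr2"), each = 50))
  X <- matrix(rnorm(100 * 8, sd = 0.8), 100, 8,
              dimnames = list(names(ann), paste0("c", 1:8)))
  e <- ecnMatrix(estimateECN(X, ann, windowRadius = 3, zeroThreshold = 0.5))
  expect_false(any(abs(e) > 0 & abs(e) < 0.5))
})

test_that("the chromosomal instability index is the mean absolute ECN", {
  e <- cbind(cin = c(1, 0, -1, 0), flat = c(0, 0, 0, 0))
  expect_equal(unname(cinIndex(e)), c(0.5, 0))
})

test_that("shuffling gene positions is a seeded bijection", {
  ann <- simulateGenome(3, 30, seed = 2)
  s1 <- shuffleGenePositions(ann, seed = 5)
  s2 <- shuffleGenePositions(ann, seed = 5)
  expect_identical(names(s1), names(s2))
  expect_setequal(names(s1), names(ann))
  expect_identical(GenomicRanges::start(s1), GenomicRanges::start(ann))
  expect_false(identical(names(s1), names(ann)))
})

test_that("shuffling destroys the chromosome-scale block structure", {
  gn <- simulateGenome(8, 100, seed = 3)
  sce <- simulateCinExperiment(gn, nRef = 20, nTest = 25,
                               missegregationRate = 0.3, seed = 4)
  ecn <- runEcnPipeline(sce)
  lag1 <- function(e) {
    mean(apply(e, 2, function(v) {
      if (stats::sd(v) == 0) return(0)
      stats::cor(v[-1], v[-length(v)])
    }))
  }
  testCells <- colnames(sce)[sce$label == "test"]
  acBefore <- lag1(ecnMatrix(ecn)[, testCells])
  # same relative expression, shuffled gene-to-position map
  shuf <- GenomicRanges::sort(shuffleGenePositions(
    SummarizedExperiment::rowRanges(sce), seed = 6))
  sceN <- normalizeCounts(sce)
  Xfull <- relativeExpression(sceN, buildReferenceProfile(sceN))
  ecnS <- estimateECN(Xfull, shuf)
  acAfter <- lag1(ecnMatrix(ecnS)[, testCells])
  expect_lt(acAfter, 0.5 * acBefore)
})

test_that("reference cells score below CIN cells on the instability index", {
  gn <- simulateGenome(8, 100, seed = 3)
  for (s in c(101, 202, 303)) {
    sce <- simulateCinExperiment(gn, nRef = 25, nTest = 25,
                                 missegregationRate = 0.3, seed = s)
    ci <- cinIndex(runEcnPipeline(sce))
    isRef <- sce$label == "reference"
    expect_lt(median(ci[isRef]), median(ci[!isRef]))
  }
})

test_that("chromosome events are called from mean chromosome ECN", {
  ann <- toyAnnotation(rep(c("chr1", "chr2"), each = 4))
  X <- matrix(c(rep(1, 4), rep(0, 4), rep(-1, 4), rep(0, 4)), ncol = 2,
              dimnames = list(names(ann), c("gainCell", "lossCell")))
  ecn <- estimateECN(X, ann, windowRadius = 1)
  calls <- callChromosomeEvents(ecn)
  getCall <- function(cell, chr) {
    as.character(calls$call[calls$cell == cell & calls$chromosome == chr])
  }
  expect_identical(getCall("gainCell", "chr1"), "gain")
  expect_identical(getCall("gainCell", "chr2"), "neutral")
  expect_identical(getCall("lossCell", "chr1"), "loss")

  frac <- chromosomeCallFractions(
    calls, stats::setNames(c("test", "reference"),
                           c("gainCell", "lossCell")))
  gainRow <- frac[frac$chromosome == "chr1" & frac$label == "test" &
                    frac$call == "gain", ]
  expect_equal(gainRow$fraction, 1)
})

test_that("simulated whole-chromosome events recover log2 dosage", {
  gn <- simulateGenome(8, 120, seed = 41)
  sce <- simulateCinExperiment(
    gn, nRef = 40, nTest = 40, missegregationRate = 0,
    clonalEvents = c(chr1 = 4, chr2 = 1), clonalFraction = 1,
    config = simTruthConfig(bufferedFraction = 0, dropout = 0), seed = 42)
  ecn <- runEcnPipeline(sce)
  chrom <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(ecn)))
  testCells <- colnames(sce)[sce$label == "test"]
  e <- ecnMatrix(ecn)
  expect_lt(abs(mean(e[chrom == "chr1", testCells]) - 1), 0.15)
  expect_lt(abs(mean(e[chrom == "chr2", testCells]) + 1), 0.15)
  calls <- callChromosomeEvents(ecn)
  tc <- calls[calls$cell %in% testCells, ]
  expect_gt(mean(tc$call[tc$chromosome == "chr1"] == "gain"), 0.9)
  expect_gt(mean(tc$call[tc$chromosome == "chr2"] == "loss"), 0.9)
})
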