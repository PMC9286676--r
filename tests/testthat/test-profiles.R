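test_that("aggregation reproduces hand-computed group means and pct-positive", {
  counts <- matrix(c(0, 0, 1, 2,
                     0, 0, 0, 0,
                     5, 5, 5, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:4)))
  lc <- matrix(c(0, 0, 2, 4,
                 0, 0, 0, 0,
                 1, 1, 1, 1), nrow = 3, byrow = TRUE,
               dimnames = dimnames(counts))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
                  logcounts = as(Matrix::Matrix(lc, sparse = TRUE),
                                 "CsparseMatrix")),
    colData = S4Vectors::DataFrame(group = rep("T1", 4),
                                   row.names = paste0("c", 1:4)))
  pr <- aggregateProfile(sce)
  expect_equal(avgExpr(pr)["gA", "T1"], 1.5)       # mean(0,0,2,4)
  expect_equal(pctPositive(pr)["gA", "T1"], 50)
  expect_equal(avgExpr(pr)["gB", "T1"], 0)         # absent everywhere
  expect_equal(pctPositive(pr)["gB", "T1"], 0)
  expect_equal(avgExpr(pr)["gC", "T1"], 1)         # shared value v
  expect_equal(pctPositive(pr)["gC", "T1"], 100)
  expect_equal(unname(cellCounts(pr)), 4L)
})

test_that("aggregation commutes with cell permutation and orders groups canonically", {
  sce <- makeTinySce(seed = 13, nGroups = 13, cellsPerGroup = 15,
                     nGenes = 40)
  pr <- aggregateProfile(sce)
  expect_identical(colnames(avgExpr(pr)), hippocampalSubclasses)
  perm <- sample(ncol(sce))
  pr2 <- aggregateProfile(sce[, perm])
  expect_equal(avgExpr(pr2), avgExpr(pr), tolerance = 1e-12)
  expect_equal(pctPositive(pr2), pctPositive(pr), tolerance = 1e-12)
  expect_equal(sum(cellCounts(pr)), ncol(sce))
})

test_that("pct-positive is invariant to the normalization scale factor", {
  raw <- simulateCounts(simConfig(nGroups = 2, cellsPerGroup = 30,
                                  nGenes = 30, seed = 6))
  a <- aggregateProfile(logNormalize(qcFilter(raw, minFeatures = 1),
                                     scaleFactor = 10000))
  b <- aggregateProfile(logNormalize(qcFilter(raw, minFeatures = 1),
                                     scaleFactor = 500))
  expect_identical(pctPositive(a), pctPositive(b))
})

test_that("profile z-scores are centered, unit-scaled and zero for flat rows", {
  pr <- methods::new("TypeProfile",
    x = matrix(c(1, 2, 3,
                 4, 4, 4), 2, 3, byrow = TRUE,
               dimnames = list(c("gA", "gB"), c("T1", "T2", "T3"))),
    pctPos = matrix(50, 2, 3,
                    dimnames = list(c("gA", "gB"), c("T1", "T2", "T3"))),
    nCells = setNames(c(5L, 5L, 5L), c("T1", "T2", "T3")))
  pr <- scoreProfile(pr)
  expect_equal(unname(zScores(pr)["gA", ]), c(-1, 0, 1))
  expect_equal(unname(zScores(pr)["gB", ]), c(0, 0, 0))
  expect_lt(abs(mean(zScores(pr)["gA", ])), 1e-12)

  one <- methods::new("TypeProfile",
    x = matrix(1, 2, 1, dimnames = list(c("a", "b"), "T1")),
    pctPos = matrix(0, 2, 1, dimnames = list(c("a", "b"), "T1")),
    nCells = setNames(1L, "T1"))
  expect_error(scoreProfile(one), "two groups")
})

test_that("splitBy crosses keys, omits absent combinations, dedupes keys", {
  sce <- makeTinySce(seed = 9, nGroups = 3, cellsPerGroup = 30, nGenes = 20)
  crossed <- splitBy(sce, c("group", "sex"))
  key <- S4Vectors::metadata(crossed)$compositeKey
  expect_equal(key, "group.sex")
  labs <- unique(SummarizedExperiment::colData(crossed)[[key]])
  present <- unique(paste(sce$group, sce$sex, sep = "."))
  expect_setequal(labs, present)
  pr <- aggregateProfile(crossed, key = key)
  expect_equal(ncol(avgExpr(pr)), length(present))

  # removing one sex from one group drops exactly that combination
  drop <- !(sce$group == "Group01" & sce$sex == "F")
  crossed2 <- splitBy(sce[, drop], c("group", "sex"))
  labs2 <- unique(SummarizedExperiment::colData(crossed2)[[key]])
  expect_false("Group01.F" %in% labs2)

  same <- splitBy(sce, c("group", "group"))
  expect_identical(SummarizedExperiment::colData(same)[["group"]],
                   sce$group)
  expect_equal(S4Vectors::metadata(same)$compositeKey, "group")

  expect_error(splitBy(sce, c("group", "missing")), "not found")
})

test_that("paired gene contrast matches signed-rank enumeration", {
  x <- matrix(0, 2, 13, dimnames = list(c("gA", "gB"),
                                        hippocampalSubclasses))
  x["gA", ] <- seq(0.1, 1.3, by = 0.1) * 2   # gA > gB everywhere
  x["gB", ] <- seq(0.1, 1.3, by = 0.1)
  pr <- methods::new("TypeProfile", x = x,
                     pctPos = x * 0, nCells = setNames(rep(1L, 13),
                                                       colnames(x)))
  ct <- pairedGeneContrast(pr, "gA", "gB")
  expect_equal(ct$p, 2 / 2^13, tolerance = 1e-12)
  expect_equal(ct$p, oracleSignedRankP(x["gA", ], x["gB", ]),
               tolerance = 1e-12)
  expect_gt(ct$log2fc, 0)

  tie <- pairedGeneContrast(pr, "gA", "gA")
  expect_equal(tie$p, 1)
  expect_equal(tie$log2fc, 0)

  # 3 groups, differences (+1, +2, -3): exhaustive 2^3 sign enumeration
  x3 <- matrix(c(2, 3, 1,
                 1, 1, 4), 2, 3, byrow = TRUE,
               dimnames = list(c("gA", "gB"), c("T1", "T2", "T3")))
  pr3 <- methods::new("TypeProfile", x = x3, pctPos = x3 * 0,
                      nCells = setNames(rep(1L, 3), colnames(x3)))
  ct3 <- pairedGeneContrast(pr3, "gA", "gB")
  expect_equal(ct3$p, oracleSignedRankP(c(1, 2, -3)), tolerance = 1e-12)
})

test_that("within-group contrast is exact and rank-invariant to scaling", {
  lc <- matrix(c(1, 2, 0,
                 3, 4, 0), 2, 3, byrow = TRUE,
               dimnames = list(c("gA", "gB"), paste0("c", 1:3)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(Matrix::Matrix(lc, sparse = TRUE),
                              "CsparseMatrix"),
                  logcounts = as(Matrix::Matrix(lc, sparse = TRUE),
                                 "CsparseMatrix")),
    colData = S4Vectors::DataFrame(group = c("T1", "T1", "T2"),
                                   row.names = paste0("c", 1:3)))
  ct <- geneWithinGroupContrast(sce, "gA", "gB", "T1")
  expect_equal(ct$p, 1 / 3, tolerance = 1e-12)
  expect_equal(ct$p, oracleRankSumP(c(1, 2), c(3, 4)), tolerance = 1e-12)

  doubled <- sce
  SummarizedExperiment::assay(doubled, "logcounts") <-
    SummarizedExperiment::assay(sce, "logcounts") * 2
  ct2 <- geneWithinGroupContrast(doubled, "gA", "gB", "T1")
  expect_equal(ct2$p, ct$p)

  same <- geneWithinGroupContrast(sce, "gA", "gA", "T1")
  expect_equal(same$p, 1)
  expect_equal(same$log2fc, 0)
  expect_error(geneWithinGroupContrast(sce, "gA", "gB", "T2"), "fewer than 2")
})
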