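# helper: profile object straight from an average-expression matrix
profileFromX <- function(x) {
  methods::new("TypeProfile", x = x,
               pctPos = matrix(0, nrow(x), ncol(x), dimnames = dimnames(x)),
               nCells = setNames(rep(1L, ncol(x)), colnames(x)))
}

test_that("raw coupling matches its closed form, symmetry and epsilon floor", {
  x <- matrix(c(1, 10,
                0.5, 2,
                0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("r", "gA", "gB"), c("T1", "T2")))
  pr <- profileFromX(x)
  k <- couplingRaw(pr, "r", c("gA", "gB"))
  get <- function(g, t) k$k[k$gene == g & k$group == t]
  expect_equal(get("gA", "T1"), log10(1 * 0.5), tolerance = 1e-12)
  expect_equal(get("gA", "T2"), log10(10 * 2), tolerance = 1e-12)
  # x_it = x_jt = 10 -> k = 2
  x2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("r", "g"), "T1"))
  expect_equal(couplingRaw(profileFromX(x2), "r", "g")$k, 2,
               tolerance = 1e-12)
  # x_it = 0.5, x_jt = 2 -> k = 0, and swapping i and j gives the same value
  x3 <- matrix(c(2, 0.5), 2, 1, dimnames = list(c("r", "g"), "T1"))
  expect_equal(couplingRaw(profileFromX(x3), "r", "g")$k, 0,
               tolerance = 1e-12)
  x3swap <- matrix(c(0.5, 2), 2, 1, dimnames = list(c("r", "g"), "T1"))
  expect_equal(couplingRaw(profileFromX(x3swap), "r", "g")$k,
               couplingRaw(profileFromX(x3), "r", "g")$k, tolerance = 1e-12)
  # zero average floored at epsilon: x = 0 and 1 -> k = -6
  expect_equal(get("gB", "T1"), -6, tolerance = 1e-12)
  expect_error(couplingRaw(pr, "r", "gA", epsilon = 0), "positive")
  expect_error(couplingRaw(pr, "missing", "gA"), "receptor")
  expect_warning(couplingRaw(pr, "r", c("gA", "nope")), "skipped")
})

test_that("min-max normalization attains {0,1}, zeros constant blocks", {
  k <- data.frame(receptor = "r", gene = c("a", "b", "c"), group = "T1",
                  k = c(-1, 0, 1))
  out <- normalizeCoupling(k)
  expect_equal(out$cNorm, c(0, 0.5, 1))
  flat <- normalizeCoupling(data.frame(receptor = "r",
                                       gene = c("a", "b"), group = "T1",
                                       k = c(2, 2)))
  expect_equal(flat$cNorm, c(0, 0))
  expect_error(normalizeCoupling(data.frame()), "empty")
})

test_that("coupling equals the spreadsheet-style oracle on a hand grid", {
  x <- matrix(c(1, 2, 4,
                8, 1, 2,
                1, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "r"), c("T1", "T2", "T3")))
  pr <- profileFromX(x)
  res <- couplingScore(pr, receptors = "r", geneSet = c("gA", "gB"),
                       setName = "toy")
  rec <- couplingRecords(res)
  oracle <- oracleCoupling(x, "r", c("gA", "gB"))
  m <- merge(rec, oracle, by = c("gene", "group"))
  expect_equal(nrow(m), 6L)
  expect_equal(m$k.x, m$k.y, tolerance = 1e-12)
  expect_equal(m$cNorm.x, m$cNorm.y, tolerance = 1e-12)
  expect_equal(min(rec$cNorm), 0)
  expect_equal(max(rec$cNorm), 1)
})

test_that("random grids match the oracle; symmetry and monotonicity hold", {
  set.seed(81)
  for (i in 1:50) {
    nG <- sample(2:3, 1); nT <- sample(2:3, 1)
    x <- matrix(round(runif((nG + 1) * nT, 0, 5), 3), nG + 1, nT,
                dimnames = list(c("r", paste0("g", seq_len(nG))),
                                paste0("T", seq_len(nT))))
    pr <- profileFromX(x)
    rec <- couplingRecords(couplingScore(pr, receptors = "r",
                                         geneSet = paste0("g", seq_len(nG))))
    oracle <- oracleCoupling(x, "r", paste0("g", seq_len(nG)))
    m <- merge(rec, oracle, by = c("gene", "group"))
    expect_equal(m$k.x, m$k.y, tolerance = 1e-12)
    expect_equal(m$cNorm.x, m$cNorm.y, tolerance = 1e-12)

    # monotonicity: raising one average above epsilon never lowers k or its
    # cNorm within the same normalization block (other entries fixed)
    xx <- x
    cell <- c(sample(nG, 1) + 1, sample(nT, 1))
    xx[cell[1], cell[2]] <- x[cell[1], cell[2]] + 1
    rec2 <- couplingRecords(couplingScore(profileFromX(xx), receptors = "r",
                                          geneSet = paste0("g", seq_len(nG))))
    g <- rownames(x)[cell[1]]; t <- colnames(x)[cell[2]]
    pick <- function(r) r[r$gene == g & r$group == t, ]
    expect_gte(pick(rec2)$k, pick(rec)$k)
  }

  # scale equivariance: x -> a*x shifts every k by 2*log10(a), cNorm unchanged
  x <- matrix(runif(12, 0.1, 4), 4, 3,
              dimnames = list(c("r", "g1", "g2", "g3"), c("A", "B", "C")))
  a <- 7.3
  r1 <- couplingRecords(couplingScore(profileFromX(x), "r",
                                      geneSet = c("g1", "g2", "g3")))
  r2 <- couplingRecords(couplingScore(profileFromX(x * a), "r",
                                      geneSet = c("g1", "g2", "g3")))
  expect_equal(r2$k - r1$k, rep(2 * log10(a), nrow(r1)), tolerance = 1e-10)
  expect_equal(r2$cNorm, r1$cNorm, tolerance = 1e-10)
})

test_that("per-group scope normalizes each cell type separately", {
  x <- matrix(c(1, 10,
                2, 20,
                4, 40), nrow = 3, byrow = TRUE,
              dimnames = list(c("r", "g1", "g2"), c("T1", "T2")))
  res <- couplingScore(profileFromX(x), "r", geneSet = c("g1", "g2"),
                       scope = "per_group")
  rec <- couplingRecords(res)
  for (t in c("T1", "T2")) {
    block <- rec$cNorm[rec$group == t]
    expect_equal(min(block), 0)
    expect_equal(max(block), 1)
  }
})

test_that("shortlisting applies a strict threshold and the receptor rule", {
  rec <- data.frame(
    receptor = rep(c("Nr3c1", "Nr3c2"), each = 2),
    gene = rep(c("g1", "g2"), 2),
    group = "DG",
    k = 0,
    cNorm = c(0.59, 0.61, 0.59, 0.59),
    set = "s")
  res <- methods::new("CouplingResult", records = rec, setName = "s",
                      receptors = c("Nr3c1", "Nr3c2"), epsilon = 1e-6,
                      scope = "set_by_group_grid")
  none <- shortlistCoupling(res, threshold = 0.61)
  expect_equal(nrow(none), 0L)
  either <- shortlistCoupling(res, threshold = 0.6)
  expect_equal(nrow(either), 1L)
  expect_equal(either$gene, "g2")
  expect_equal(either$receptors, "Nr3c1")
  both <- shortlistCoupling(res, threshold = 0.6, rule = "both")
  expect_equal(nrow(both), 0L)
  expect_error(shortlistCoupling(res, threshold = 1.5), "0, 1")

  # random block: shortlist equals a brute-force scan
  set.seed(82)
  rnd <- data.frame(
    receptor = sample(c("Nr3c1", "Nr3c2"), 80, TRUE),
    gene = sample(paste0("g", 1:20), 80, TRUE),
    group = sample(c("DG", "CA3"), 80, TRUE),
    k = 0, cNorm = runif(80), set = "s")
  rnd <- rnd[!duplicated(rnd[c("receptor", "gene", "group")]), ]
  resR <- methods::new("CouplingResult", records = rnd, setName = "s",
                       receptors = c("Nr3c1", "Nr3c2"), epsilon = 1e-6,
                       scope = "set_by_group_grid")
  sl <- shortlistCoupling(resR, threshold = 0.6)
  brute <- unique(rnd[rnd$cNorm > 0.6, c("gene", "group")])
  expect_equal(nrow(sl), nrow(brute))
  expect_setequal(paste(sl$gene, sl$group),
                  paste(brute$gene, brute$group))
})

test_that("heatmap matrices honor orderings and round-trip to full precision", {
  x <- matrix(runif(12, 0.1, 3), 4, 3,
              dimnames = list(c("r", "g1", "g2", "g3"), c("A", "B", "C")))
  res <- couplingScore(profileFromX(x), "r", geneSet = c("g1", "g2", "g3"),
                       setName = "toy")
  m <- couplingMatrix(res, "r")
  expect_equal(dim(m), c(3L, 3L))
  rec <- couplingRecords(res)
  expect_equal(m["g2", "B"], rec$cNorm[rec$gene == "g2" & rec$group == "B"])
  flipped <- couplingMatrix(res, "r", rowOrder = c("g3", "g1", "g2"))
  expect_equal(flipped["g3", ], m["g3", ])
  expect_warning(couplingMatrix(res, "r", rowOrder = c("g1", "ghost")),
                 "missing")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeCouplingTable(res, tsv)
  back <- readCouplingTable(tsv)
  expect_identical(back$cNorm, rec$cNorm)
  expect_identical(back$k, rec$k)
})

test_that("planted co-expression is recovered as the argmax group", {
  sce <- makeTinySce(seed = 31, nGroups = 4, cellsPerGroup = 200,
                     nGenes = 100,
                     plantedPairs = list(list(geneA = "Nr3c1",
                                              geneB = "Gene0030",
                                              group = "Group03",
                                              fold = 50)))
  pr <- aggregateProfile(sce)
  rec <- couplingRecords(couplingScore(
    pr, receptors = "Nr3c1",
    geneSet = sprintf("Gene%04d", c(10, 20, 30, 40))))
  sub <- rec[rec$gene == "Gene0030", ]
  expect_equal(sub$group[which.max(sub$cNorm)], "Group03")
})
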