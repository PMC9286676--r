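# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately share no code with the package:
# everything is re-derived by enumeration or plain loops.

# two-sided signed-rank p by enumerating all 2^n sign assignments
oracleSignedRankP <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- drop(signs %*% r)
  min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
}

# two-sided rank-sum p by enumerating all C(n, nx) group assignments
oracleRankSumP <- function(x, y) {
  v <- c(x, y)
  nx <- length(x)
  r <- rank(v)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(v), nx)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
}

# spreadsheet-style coupling oracle: raw log10 products and grid min-max
oracleCoupling <- function(x, receptor, genes, eps = 1e-6) {
  out <- data.frame()
  for (g in genes) {
    for (t in colnames(x)) {
      k <- log10(max(x[g, t], eps) * max(x[receptor, t], eps))
      out <- rbind(out, data.frame(gene = g, group = t, k = k))
    }
  }
  rng <- range(out$k)
  out$cNorm <- if (rng[2] > rng[1]) (out$k - rng[1]) / (rng[2] - rng[1]) else 0
  out
}

# exhaustive per-gene consensus criteria, written as plain loops
oracleConsensusCalls <- function(ev, minStudies = 3L, requireInhouse = TRUE) {
  called <- character(0)
  for (g in sort(unique(ev$gene))) {
    rows <- ev[ev$gene == g, , drop = FALSE]
    tx <- rows[rows$source_type %in%
                 c("meta_transcriptomic", "inhouse_rnaseq"), , drop = FALSE]
    chip <- rows[rows$source_type == "chipseq", , drop = FALSE]
    c1 <- sum(rows$source_type == "meta_transcriptomic") >= 1
    c2 <- !requireInhouse || sum(rows$source_type == "inhouse_rnaseq") >= 1
    c3 <- nrow(tx) >= 1 && length(unique(tx$direction)) == 1
    c4 <- nrow(chip) >= 1
    c5 <- length(unique(tx$study_id)) >= minStudies
    if (c1 && c2 && c3 && c4 && c5) called <- c(called, g)
  }
  called
}

# schema-valid random evidence table, independent of simulateEvidence()
randomEvidenceTable <- function(nGenes = 8L) {
  rows <- data.frame()
  metaStudies <- sprintf("m%02d", 1:6)
  for (i in seq_len(nGenes)) {
    g <- sprintf("G%03d", i)
    nMeta <- sample(0:4, 1)
    if (nMeta > 0) {
      oneDir <- sample(c(TRUE, FALSE), 1)
      dirs <- if (oneDir) rep(sample(c("up", "down"), 1), nMeta) else
        sample(c("up", "down"), nMeta, replace = TRUE)
      rows <- rbind(rows, data.frame(
        gene = g, source_type = "meta_transcriptomic",
        study_id = sample(metaStudies, nMeta), direction = dirs,
        binding = "none"))
    }
    if (sample(c(TRUE, FALSE), 1)) {
      rows <- rbind(rows, data.frame(
        gene = g, source_type = "inhouse_rnaseq", study_id = "ih",
        direction = sample(c("up", "down"), 1), binding = "none"))
    }
    chip <- sample(c("none", "GR", "MR", "GRMR", "both"), 1)
    if (chip == "GR" || chip == "GRMR")
      rows <- rbind(rows, data.frame(gene = g, source_type = "chipseq",
                                     study_id = "chipGR", direction = "na",
                                     binding = "GR"))
    if (chip == "MR" || chip == "GRMR")
      rows <- rbind(rows, data.frame(gene = g, source_type = "chipseq",
                                     study_id = "chipMR", direction = "na",
                                     binding = "MR"))
    if (chip == "both")
      rows <- rbind(rows, data.frame(gene = g, source_type = "chipseq",
                                     study_id = "chipB", direction = "na",
                                     binding = "both"))
  }
  rows
}

# small normalized dataset shared across tests
makeTinySce <- function(seed = 42L, nGroups = 3L, cellsPerGroup = 40L,
                        nGenes = 60L, ...) {
  sce <- simulateCounts(simConfig(nGroups = nGroups,
                                  cellsPerGroup = cellsPerGroup,
                                  nGenes = nGenes, seed = seed, ...))
  logNormalize(qcFilter(sce, minCells = 1, minFeatures = 1))
}
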