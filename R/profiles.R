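# group levels in canonical display order; falls back to lexicographic
.orderGroups <- function(labels) {
  u <- unique(as.character(labels))
  if (all(u %in% hippocampalSubclasses)) {
    hippocampalSubclasses[hippocampalSubclasses %in% u]
  } else {
    sort(u)
  }
}

#' Aggregate a normalized matrix into per-group expression profiles
#'
#' Collapses cells into cell-type profiles: for each gene i and group t the
#' arithmetic mean \eqn{x_{it}} of log-normalized expression over the cells
#' of t, and the percent-positive (share of cells with raw count > 0, on a
#' 0-100 scale; computed from the raw counts, so it is independent of
#' normalization parameters). Groups with zero cells are dropped with a
#' warning. Column order is the canonical hippocampal subclass order when
#' all labels belong to it, else lexicographic.
#'
#' @param sce A SingleCellExperiment with `counts` and `logcounts` assays
#'   and the grouping column in `colData`.
#' @param key colData column defining the groups (default `"group"`).
#' @return A \linkS4class{TypeProfile}.
#' @seealso [scoreProfile()], [couplingScore()], [profileTable()]
#' @export
aggregateProfile <- function(sce, key = "group") {
  cd <- SummarizedExperiment::colData(sce)
  if (!key %in% names(cd)) stop("annotation column not found: ", key)
  labels <- as.character(cd[[key]])
  if (anyNA(labels)) stop("every cell must be annotated for '", key, "'")
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
    stop("run logNormalize() before profiling")
  lev <- .orderGroups(labels)
  f <- factor(labels, levels = lev)
  n <- as.integer(table(f))
  names(n) <- lev
  if (any(n == 0L)) {
    warning("dropping empty groups: ",
            paste(lev[n == 0L], collapse = ", "))
    lev <- lev[n > 0L]
    f <- factor(labels, levels = lev)
    n <- n[lev]
  }
  # sparse-friendly group means via an indicator matrix
  ind <- Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f), x = 1,
    dims = c(length(f), length(lev))
  )
  ind <- ind %*% Matrix::Diagonal(x = 1 / n)
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  counts <- SummarizedExperiment::assay(sce, "counts")
  x <- as.matrix(lc %*% ind)
  pct <- pmin(pmax(as.matrix((counts > 0) %*% ind) * 100, 0), 100)
  dimnames(x) <- dimnames(pct) <- list(rownames(sce), lev)
  methods::new("TypeProfile", x = x, pctPos = pct, nCells = n,
               groupKey = key)
}

#' Row-standardize a profile (z-scores across groups)
#'
#' Fills the `z` slot with \eqn{z_{it} = (x_{it} - \bar x_i)/s_i}, using the
#' sample standard deviation across groups. Rows constant across groups get
#' all-zero z. Requires at least two groups.
#'
#' @param profile A \linkS4class{TypeProfile}.
#' @return The profile with `zScores()` filled.
#' @export
scoreProfile <- function(profile) {
  x <- avgExpr(profile)
  if (ncol(x) < 2L)
    stop("z-scores require at least two groups")
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  profile@z <- z
  methods::validObject(profile)
  profile
}

#' Cross annotation keys into a composite grouping
#'
#' Adds a colData column whose labels are the interaction of the requested
#' keys (e.g. `"DG.F"`), so [aggregateProfile()] can produce per-sex,
#' per-cell-type profiles. Combinations absent from the data simply do not
#' appear. Duplicate keys collapse to a single key, so the composite of a
#' key with itself equals the single-key grouping.
#'
#' @param sce An annotated SingleCellExperiment.
#' @param keys Character vector of colData columns (default
#'   `c("group", "sex")`).
#' @param sep Separator for the composite labels (default `"."`).
#' @return The SingleCellExperiment with the new column added; its name
#'   (`paste(keys, collapse = sep)`) is returned in
#'   `metadata()$compositeKey`.
#' @export
splitBy <- function(sce, keys = c("group", "sex"), sep = ".") {
  keys <- unique(keys)
  cd <- SummarizedExperiment::colData(sce)
  missing <- setdiff(keys, names(cd))
  if (length(missing))
    stop("annotation columns not found: ", paste(missing, collapse = ", "))
  newKey <- paste(keys, collapse = sep)
  labels <- do.call(paste, c(lapply(keys, function(k) as.character(cd[[k]])),
                             sep = sep))
  SummarizedExperiment::colData(sce)[[newKey]] <- labels
  md <- S4Vectors::metadata(sce)
  md$compositeKey <- newKey
  S4Vectors::metadata(sce) <- md
  sce
}

#' Paired contrast of two genes across cell-type averages
#'
#' Tests whether gene A is expressed differently from gene B across cell
#' types, pairing the per-group average expression values and applying the
#' two-sided Wilcoxon signed-rank test (exact where enumeration applies).
#' The fold change follows the [log2FoldChange()] convention on the
#' per-group averages.
#'
#' @param profile A \linkS4class{TypeProfile}.
#' @param geneA,geneB Gene names present in the profile.
#' @param fcMode Fold-change convention, see [log2FoldChange()].
#' @return A one-row data.frame with `gene_a`, `gene_b`, `log2fc`, `p`,
#'   `p_adj` (= `p` for a single test) and `test`.
#' @export
pairedGeneContrast <- function(profile, geneA, geneB,
                               fcMode = c("expm1", "logdiff")) {
  fcMode <- match.arg(fcMode)
  x <- avgExpr(profile)
  for (g in c(geneA, geneB)) {
    if (!g %in% rownames(x)) stop("gene not in profile: ", g)
  }
  if (ncol(x) < 2L) stop("paired contrast requires at least two groups")
  a <- x[geneA, ]; b <- x[geneB, ]
  if (all(a == b)) {
    return(data.frame(gene_a = geneA, gene_b = geneB, log2fc = 0,
                      p = 1, p_adj = 1, test = "wilcoxon_signed_rank",
                      stringsAsFactors = FALSE))
  }
  w <- wilcoxonSignedRank(a, b)
  data.frame(gene_a = geneA, gene_b = geneB,
             log2fc = log2FoldChange(a, b, fcMode),
             p = w$p, p_adj = w$p, test = "wilcoxon_signed_rank",
             stringsAsFactors = FALSE)
}

#' Contrast two genes within one cell type
#'
#' Two-sample Wilcoxon rank-sum test between the per-cell log-normalized
#' expression of gene A and gene B over the cells of a single group.
#'
#' @param sce A SingleCellExperiment with `logcounts` and group annotation.
#' @param geneA,geneB Gene names.
#' @param group Group label to restrict to.
#' @param key colData column holding the labels (default `"group"`).
#' @param fcMode Fold-change convention, see [log2FoldChange()].
#' @return A one-row data.frame as in [pairedGeneContrast()], with a
#'   `group` column.
#' @export
geneWithinGroupContrast <- function(sce, geneA, geneB, group,
                                    key = "group",
                                    fcMode = c("expm1", "logdiff")) {
  fcMode <- match.arg(fcMode)
  cd <- SummarizedExperiment::colData(sce)
  if (!key %in% names(cd)) stop("annotation column not found: ", key)
  cells <- which(as.character(cd[[key]]) == group)
  if (length(cells) < 2L)
    stop("group '", group, "' has fewer than 2 cells")
  for (g in c(geneA, geneB)) {
    if (!g %in% rownames(sce)) stop("gene not in matrix: ", g)
  }
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  a <- as.numeric(lc[geneA, cells])
  b <- as.numeric(lc[geneB, cells])
  if (identical(a, b)) {
    return(data.frame(gene_a = geneA, gene_b = geneB, group = group,
                      log2fc = 0, p = 1, p_adj = 1,
                      test = "wilcoxon_rank_sum", stringsAsFactors = FALSE))
  }
  w <- wilcoxonRankSum(a, b)
  data.frame(gene_a = geneA, gene_b = geneB, group = group,
             log2fc = log2FoldChange(a, b, fcMode),
             p = w$p, p_adj = w$p, test = "wilcoxon_rank_sum",
             stringsAsFactors = FALSE)
}

#' Long-format profile table
#'
#' @param profile A \linkS4class{TypeProfile} (optionally with z filled).
#' @return data.frame with columns `gene`, `group`, `x`, `pct_pos`,
#'   `n_cells`, `z` (NA when not computed).
#' @export
profileTable <- function(profile) {
  x <- avgExpr(profile)
  pct <- pctPositive(profile)
  z <- zScores(profile)
  n <- cellCounts(profile)
  out <- data.frame(
    gene = rep(rownames(x), times = ncol(x)),
    group = rep(colnames(x), each = nrow(x)),
    x = as.vector(x),
    pct_pos = as.vector(pct),
    n_cells = rep(unname(n), each = nrow(x)),
    z = if (length(z)) as.vector(z) else NA_real_,
    stringsAsFactors = FALSE
  )
  out
}
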