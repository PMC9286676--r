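#' One-vs-rest marker statistics for every group
#'
#' For each cell type, compares each gene's log-normalized expression in
#' the group against all remaining cells with the two-sided Wilcoxon
#' rank-sum test ([wilcoxonRankSum()]), reporting the fold change
#' ([log2FoldChange()] convention), the percent of expressing cells inside
#' and outside the group, and Benjamini-Hochberg adjusted p-values computed
#' across every hypothesis tested in the run.
#'
#' By default genes enter the test only when expressed in at least
#' `minPct` (fraction) of cells on one side and the absolute fold change
#' reaches `logfcThreshold`; `prefilter = FALSE` disables both filters
#' (useful for exhaustive cross-checks). Groups with fewer than
#' `minCellsPerGroup` cells are skipped with a warning.
#'
#' @param sce A SingleCellExperiment with `counts`, `logcounts` and group
#'   annotation.
#' @param key colData column defining groups (default `"group"`).
#' @param genes Genes to consider (default all).
#' @param minPct Minimum expressing fraction on either side (default 0.1).
#' @param logfcThreshold Minimum |log2 fold change| (default 0.25).
#' @param prefilter Apply the two pre-filters (default TRUE).
#' @param minCellsPerGroup Smallest testable group (default 3).
#' @param fcMode Fold-change convention, see [log2FoldChange()].
#' @return data.frame with columns `gene`, `group`, `log2fc`, `pct_in`,
#'   `pct_out` (0-100), `p`, `p_adj`, sorted by group then p.
#' @export
findGroupMarkers <- function(sce, key = "group", genes = NULL,
                             minPct = 0.1, logfcThreshold = 0.25,
                             prefilter = TRUE, minCellsPerGroup = 3L,
                             fcMode = c("expm1", "logdiff")) {
  fcMode <- match.arg(fcMode)
  cd <- SummarizedExperiment::colData(sce)
  if (!key %in% names(cd)) stop("annotation column not found: ", key)
  labels <- as.character(cd[[key]])
  groups <- .orderGroups(labels)
  if (length(groups) < 2L) stop("marker detection requires >= 2 groups")
  if (is.null(genes)) genes <- rownames(sce)
  lc <- as.matrix(SummarizedExperiment::assay(sce, "logcounts")[genes, ,
                                                                drop = FALSE])
  pos <- as.matrix(SummarizedExperiment::assay(sce, "counts")[genes, ,
                                                              drop = FALSE]) > 0
  out <- list()
  for (g in groups) {
    inGroup <- labels == g
    if (sum(inGroup) < minCellsPerGroup) {
      warning("group '", g, "' has fewer than ", minCellsPerGroup,
              " cells; skipped")
      next
    }
    pctIn <- rowMeans(pos[, inGroup, drop = FALSE]) * 100
    pctOut <- rowMeans(pos[, !inGroup, drop = FALSE]) * 100
    lfc <- vapply(genes, function(gene)
      log2FoldChange(lc[gene, inGroup], lc[gene, !inGroup], fcMode), 0)
    test <- rep(TRUE, length(genes))
    if (prefilter) {
      test <- (pmax(pctIn, pctOut) / 100 >= minPct) &
        (abs(lfc) >= logfcThreshold)
    }
    if (!any(test)) next
    p <- vapply(genes[test], function(gene)
      wilcoxonRankSum(lc[gene, inGroup], lc[gene, !inGroup])$p, 0)
    out[[g]] <- data.frame(
      gene = genes[test], group = g, log2fc = lfc[test],
      pct_in = pctIn[test], pct_out = pctOut[test], p = p,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), group = character(0),
                      log2fc = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), p = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$p_adj <- bhAdjust(res$p)
  res <- res[order(match(res$group, groups), res$p, res$gene), ]
  rownames(res) <- NULL
  res
}
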