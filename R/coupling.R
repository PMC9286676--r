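#' Raw coupling score of a receptor with a gene set
#'
#' For receptor gene j, each gene i of set S and each cell type t, the raw
#' coupling score is
#' \deqn{k_{ijt} = \log_{10}(x_{it} \cdot x_{jt})}
#' on the per-group average expression \eqn{x}. Averages are floored at
#' `epsilon` before the logarithm so that absent genes yield very low but
#' finite scores. The score is symmetric in i and j by construction.
#'
#' @param profile A \linkS4class{TypeProfile}.
#' @param receptor Receptor gene name j (must be in the profile).
#' @param geneSet Character vector of gene symbols (the set S). Members
#'   missing from the profile are reported and skipped.
#' @param epsilon Positive expression floor (default 1e-6).
#' @return Long-format data.frame with columns `receptor`, `gene`, `group`,
#'   `k`.
#' @seealso [normalizeCoupling()], [couplingScore()]
#' @export
couplingRaw <- function(profile, receptor, geneSet, epsilon = 1e-6) {
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("'epsilon' must be a positive number")
  x <- avgExpr(profile)
  if (!receptor %in% rownames(x))
    stop("receptor not in profile: ", receptor)
  geneSet <- unique(geneSet)
  missing <- setdiff(geneSet, rownames(x))
  if (length(missing)) {
    warning("gene set members missing from profile, skipped: ",
            paste(missing, collapse = ", "))
    geneSet <- setdiff(geneSet, missing)
  }
  if (!length(geneSet)) stop("no gene set members present in the profile")
  xi <- pmax(x[geneSet, , drop = FALSE], epsilon)
  xj <- pmax(x[receptor, ], epsilon)
  k <- log10(xi * rep(xj, each = nrow(xi)))
  data.frame(
    receptor = receptor,
    gene = rep(rownames(k), times = ncol(k)),
    group = rep(colnames(k), each = nrow(k)),
    k = as.vector(k),
    stringsAsFactors = FALSE
  )
}

#' Min-max normalization of coupling scores within a gene set
#'
#' Rescales the raw scores of each (receptor, set) block to [0, 1]:
#' \deqn{C_{ijt}^S = \frac{k_{ijt} - \min_S k}{\max_S k - \min_S k}.}
#' The default scope `"set_by_group_grid"` takes the minimum and maximum
#' over the whole (gene in S) x (group) grid of the receptor, matching
#' heatmaps that share one color scale across cell types; `"per_group"`
#' normalizes each cell-type column separately. A degenerate block
#' (max = min) maps to all zeros.
#'
#' @param k Long-format data.frame from [couplingRaw()] (a `set` column, if
#'   present, separates blocks).
#' @param scope `"set_by_group_grid"` (default) or `"per_group"`.
#' @return The input with a `cNorm` column added.
#' @export
normalizeCoupling <- function(k, scope = c("set_by_group_grid", "per_group")) {
  scope <- match.arg(scope)
  if (!nrow(k)) stop("empty coupling block")
  blockId <- if ("set" %in% names(k)) {
    paste(k$receptor, k$set, sep = "\r")
  } else {
    k$receptor
  }
  if (scope == "per_group") blockId <- paste(blockId, k$group, sep = "\r")
  k$cNorm <- ave(k$k, blockId, FUN = function(v) {
    rng <- range(v)
    if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else rep(0, length(v))
  })
  k
}

#' Coupling scores of receptors with a gene set
#'
#' Convenience wrapper computing [couplingRaw()] for each receptor and
#' normalizing within the set via [normalizeCoupling()].
#'
#' @inheritParams couplingRaw
#' @param receptors Character vector of receptor genes (default
#'   `c("Nr3c1", "Nr3c2")`).
#' @param setName Label for the gene set (stored in the records).
#' @inheritParams normalizeCoupling
#' @return A \linkS4class{CouplingResult}.
#' @export
#' @examples
#' sce <- simulateCounts(simConfig(nGroups = 3, cellsPerGroup = 50,
#'                                 nGenes = 30, seed = 7))
#' sce <- logNormalize(qcFilter(sce, minFeatures = 1))
#' pr <- aggregateProfile(sce)
#' res <- couplingScore(pr, geneSet = c("Gene0005", "Gene0006"),
#'                      setName = "demo")
#' head(couplingRecords(res))
couplingScore <- function(profile, receptors = c("Nr3c1", "Nr3c2"),
                          geneSet, setName = "gene_set",
                          epsilon = 1e-6,
                          scope = c("set_by_group_grid", "per_group")) {
  scope <- match.arg(scope)
  parts <- lapply(receptors, function(j)
    couplingRaw(profile, j, geneSet, epsilon))
  rec <- do.call(rbind, parts)
  rec$set <- setName
  rec <- normalizeCoupling(rec, scope)
  rec <- rec[, c("receptor", "gene", "group", "k", "cNorm", "set")]
  methods::new("CouplingResult", records = rec, setName = setName,
               receptors = receptors, epsilon = epsilon, scope = scope)
}

#' Shortlist genes by normalized coupling threshold
#'
#' Selects (gene, group) pairs whose normalized coupling score strictly
#' exceeds `threshold` for at least one receptor (`rule = "either"`, the
#' default, with passing receptors annotated per row) or for every receptor
#' in the result (`rule = "both"`).
#'
#' @param result A \linkS4class{CouplingResult} (or its records
#'   data.frame).
#' @param threshold Cutoff in [0, 1] (default 0.6).
#' @param rule `"either"` or `"both"`.
#' @return data.frame with columns `gene`, `group`, `receptors`
#'   (comma-separated passing receptors) and `n_receptors`.
#' @export
shortlistCoupling <- function(result, threshold = 0.6,
                              rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("'threshold' must lie in [0, 1]")
  rec <- if (methods::is(result, "CouplingResult")) couplingRecords(result)
         else result
  nReceptors <- length(unique(rec$receptor))
  pass <- rec[rec$cNorm > threshold, , drop = FALSE]
  if (!nrow(pass)) {
    return(data.frame(gene = character(0), group = character(0),
                      receptors = character(0), n_receptors = integer(0),
                      stringsAsFactors = FALSE))
  }
  keyed <- split(pass$receptor, paste(pass$gene, pass$group, sep = "\r"))
  keys <- do.call(rbind, strsplit(names(keyed), "\r", fixed = TRUE))
  out <- data.frame(
    gene = keys[, 1], group = keys[, 2],
    receptors = vapply(keyed, function(r) paste(sort(unique(r)),
                                                collapse = ","), ""),
    n_receptors = vapply(keyed, function(r) length(unique(r)), 0L),
    stringsAsFactors = FALSE
  )
  if (rule == "both") out <- out[out$n_receptors == nReceptors, , drop = FALSE]
  out <- out[order(out$gene, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wide coupling matrix for heatmap display
#'
#' @param result A \linkS4class{CouplingResult}.
#' @param receptor Receptor to extract.
#' @param value `"cNorm"` (default) or `"k"`.
#' @param rowOrder,colOrder Optional explicit gene/group orderings; grid
#'   cells absent from the records are filled with NA with a warning.
#' @return A genes x groups numeric matrix.
#' @export
couplingMatrix <- function(result, receptor = NULL,
                           value = c("cNorm", "k"),
                           rowOrder = NULL, colOrder = NULL) {
  value <- match.arg(value)
  rec <- couplingRecords(result)
  if (is.null(receptor)) receptor <- result@receptors[1L]
  rec <- rec[rec$receptor == receptor, , drop = FALSE]
  if (!nrow(rec)) stop("no records for receptor: ", receptor)
  genes <- if (is.null(rowOrder)) unique(rec$gene) else rowOrder
  groups <- if (is.null(colOrder)) unique(rec$group) else colOrder
  m <- matrix(NA_real_, length(genes), length(groups),
              dimnames = list(genes, groups))
  idx <- cbind(match(rec$gene, genes), match(rec$group, groups))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  m[idx[keep, , drop = FALSE]] <- rec[[value]][keep]
  if (anyNA(m)) warning("grid cells missing from records filled with NA")
  m
}

#' Write / read coupling records as TSV
#'
#' Long-format export with 17-significant-digit numeric formatting so an
#' export/import round trip reproduces the scores to full double precision.
#'
#' @param result A \linkS4class{CouplingResult}.
#' @param path Output TSV path.
#' @return `writeCouplingTable` invisibly returns `path`;
#'   `readCouplingTable` returns the records data.frame.
#' @export
writeCouplingTable <- function(result, path) {
  rec <- couplingRecords(result)
  out <- rec
  out$k <- sprintf("%.17g", rec$k)
  out$cNorm <- sprintf("%.17g", rec$cNorm)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCouplingTable
#' @export
readCouplingTable <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(receptor = "character", gene = "character",
                            group = "character", k = "numeric",
                            cNorm = "numeric", set = "character"))
}

#' Read a gene set from a one-symbol-per-line TSV
#'
#' The file's single column header names the set; each following line is
#' one gene symbol. Duplicates are removed, order preserved.
#'
#' @param path TSV path.
#' @return Character vector of symbols with attribute `setName`.
#' @export
readGeneSet <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) != 1L)
    stop("gene set file must have exactly one column: ", path)
  members <- unique(trimws(df[[1]]))
  members <- members[members != ""]
  if (!length(members)) stop("empty gene set: ", path)
  structure(members, setName = names(df)[1])
}
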