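#' Read a sparse count matrix from Matrix Market + identifier files
#'
#' Loads a genes x cells raw count matrix from a Matrix Market coordinate
#' file with companion `features.tsv` (columns `gene_id`, `symbol`) and
#' `barcodes.tsv` (column `cell_id`) files, checking that declared
#' dimensions, identifier counts and value ranges are consistent.
#'
#' @param mtxPath Path to the `.mtx` coordinate file (1-based indices,
#'   genes as rows, cells as columns).
#' @param featuresPath Path to the tab-separated feature table with header.
#' @param barcodesPath Path to the tab-separated barcode table with header.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay, row names from feature symbols and column
#'   names from barcodes.
#' @seealso [writeFixture()], [readCellAnnotation()], [loadDataset()]
#' @export
readCounts <- function(mtxPath, featuresPath, barcodesPath) {
  for (p in c(mtxPath, featuresPath, barcodesPath)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  m <- Matrix::readMM(mtxPath)
  features <- read.delim(featuresPath, header = TRUE,
                         stringsAsFactors = FALSE)
  barcodes <- read.delim(barcodesPath, header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "symbol") %in% names(features)))
    stop("features file must have columns 'gene_id' and 'symbol': ",
         featuresPath)
  if (!"cell_id" %in% names(barcodes))
    stop("barcodes file must have a 'cell_id' column: ", barcodesPath)
  if (nrow(features) != nrow(m))
    stop("matrix header declares ", nrow(m), " genes but features file has ",
         nrow(features), " rows")
  if (nrow(barcodes) != ncol(m))
    stop("matrix header declares ", ncol(m), " cells but barcodes file has ",
         nrow(barcodes), " rows")
  dup <- features$symbol[duplicated(features$symbol)]
  if (length(dup))
    stop("duplicate gene symbols in features file: ",
         paste(unique(dup), collapse = ", "))
  dup <- barcodes$cell_id[duplicated(barcodes$cell_id)]
  if (length(dup))
    stop("duplicate cell ids in barcodes file: ",
         paste(unique(dup), collapse = ", "))
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (length(m@x) && any(m@x < 0)) {
    bad <- which(m@x < 0)[1L]
    stop("negative count entry in ", mtxPath, " (stored entry #", bad, ")")
  }
  dimnames(m) <- list(features$symbol, barcodes$cell_id)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(features, row.names = features$symbol),
    colData = S4Vectors::DataFrame(cell_id = barcodes$cell_id,
                                   row.names = barcodes$cell_id)
  )
}

#' Read a per-cell annotation table
#'
#' @param path Tab-separated file with header; requires columns `cell_id`
#'   and `group`, and optionally `sex` (`F`/`M`/`unknown`), `region`,
#'   `subcluster`. Missing optional columns are filled with `"unknown"`.
#' @return A data.frame keyed by `cell_id`.
#' @export
readCellAnnotation <- function(path) {
  ann <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "group") %in% names(ann)))
    stop("annotation must have columns 'cell_id' and 'group': ", path)
  if (anyDuplicated(ann$cell_id))
    stop("duplicate cell ids in annotation: ", path)
  for (col in c("sex", "region", "subcluster")) {
    if (!col %in% names(ann)) ann[[col]] <- "unknown"
  }
  bad <- setdiff(unique(ann$sex), c("F", "M", "unknown"))
  if (length(bad))
    stop("invalid 'sex' values in annotation: ", paste(bad, collapse = ", "))
  ann
}

#' Load a complete annotated dataset
#'
#' Reads counts and annotation and aligns them: every matrix cell must have
#' exactly one annotation row and vice versa.
#'
#' @inheritParams readCounts
#' @param annotationPath Path to the annotation TSV
#'   (see [readCellAnnotation()]).
#' @return An annotated [SingleCellExperiment::SingleCellExperiment].
#' @export
loadDataset <- function(mtxPath, featuresPath, barcodesPath, annotationPath) {
  sce <- readCounts(mtxPath, featuresPath, barcodesPath)
  ann <- readCellAnnotation(annotationPath)
  missing <- setdiff(colnames(sce), ann$cell_id)
  if (length(missing))
    stop("cells missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  extra <- setdiff(ann$cell_id, colnames(sce))
  if (length(extra))
    stop("annotation rows with no matching cell: ",
         paste(utils::head(extra, 5), collapse = ", "))
  ann <- ann[match(colnames(sce), ann$cell_id), , drop = FALSE]
  SummarizedExperiment::colData(sce) <-
    S4Vectors::DataFrame(ann, row.names = ann$cell_id)
  sce
}

#' Write a count matrix and annotation as a Matrix Market fixture
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `annotation.tsv`
#' into a directory, in the layout [readCounts()] and [loadDataset()]
#' consume. Round-trip reading reproduces the sparse matrix exactly.
#'
#' @param sce A SingleCellExperiment with a `counts` assay.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named character vector of file paths written.
#' @export
writeFixture <- function(sce, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  counts <- SummarizedExperiment::assay(sce, "counts")
  paths <- c(
    matrix = file.path(dir, "matrix.mtx"),
    features = file.path(dir, "features.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"),
    annotation = file.path(dir, "annotation.tsv")
  )
  Matrix::writeMM(methods::as(methods::as(counts, "generalMatrix"),
                              "CsparseMatrix"), paths["matrix"])
  rd <- SummarizedExperiment::rowData(sce)
  features <- data.frame(
    gene_id = if ("gene_id" %in% names(rd)) rd$gene_id else rownames(sce),
    symbol = rownames(sce), stringsAsFactors = FALSE
  )
  write.table(features, paths["features"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cd <- SummarizedExperiment::colData(sce)
  write.table(data.frame(cell_id = colnames(sce)), paths["barcodes"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  col <- function(name, default) {
    if (name %in% names(cd)) as.character(cd[[name]])
    else rep(default, ncol(sce))
  }
  ann <- data.frame(
    cell_id = colnames(sce),
    group = col("group", "all"),
    sex = col("sex", "unknown"),
    region = col("region", "unknown"),
    subcluster = col("subcluster", "unknown"),
    stringsAsFactors = FALSE
  )
  write.table(ann, paths["annotation"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Subset cells to selected groups
#'
#' Retains only cells whose group label is in `keepGroups`, leaving the gene
#' axis untouched; the annotation is filtered in lockstep with the matrix
#' columns.
#'
#' @param sce An annotated SingleCellExperiment.
#' @param keepGroups Non-empty character vector of group labels to keep.
#' @param key The colData column holding the labels (default `"group"`).
#' @return The subset SingleCellExperiment.
#' @export
subsetCells <- function(sce, keepGroups, key = "group") {
  if (!length(keepGroups)) stop("'keepGroups' must be non-empty")
  if (!key %in% names(SummarizedExperiment::colData(sce)))
    stop("annotation column not found: ", key)
  labels <- SummarizedExperiment::colData(sce)[[key]]
  keep <- labels %in% keepGroups
  if (!any(keep))
    stop("no cells belong to the requested groups: ",
         paste(keepGroups, collapse = ", "))
  sce[, keep]
}

#' Quality-control filtering of cells and genes
#'
#' Removes cells detecting fewer than `minFeatures` genes (raw count > 0),
#' then genes detected in fewer than `minCells` of the retained cells —
#' the creation-time semantics of the usual single-cell loading parameters
#' (defaults `minCells = 1`, `minFeatures = 100`). At the default
#' `minCells = 1` the operation is idempotent, because dropping genes that
#' no retained cell detects cannot change any cell's detected-gene count;
#' for `minCells > 1` a second application may remove further cells.
#'
#' @param sce A SingleCellExperiment with a `counts` assay.
#' @param minCells Minimum number of cells a gene must be detected in.
#' @param minFeatures Minimum number of detected genes per cell.
#' @return The filtered SingleCellExperiment; the number of cells and genes
#'   removed is recorded in `metadata(sce)$qcFilter`.
#' @export
qcFilter <- function(sce, minCells = 1L, minFeatures = 100L) {
  if (minCells < 0 || minFeatures < 0)
    stop("QC thresholds must be non-negative")
  counts <- SummarizedExperiment::assay(sce, "counts")
  detectedPerCell <- Matrix::colSums(counts > 0)
  keepCells <- detectedPerCell >= minFeatures
  if (!any(keepCells))
    stop("QC removed every cell (minFeatures = ", minFeatures, ")")
  countsKept <- counts[, keepCells, drop = FALSE]
  detectedPerGene <- Matrix::rowSums(countsKept > 0)
  keepGenes <- detectedPerGene >= minCells
  out <- sce[keepGenes, keepCells]
  md <- S4Vectors::metadata(out)
  md$qcFilter <- list(
    cellsRemoved = sum(!keepCells), genesRemoved = sum(!keepGenes),
    minCells = minCells, minFeatures = minFeatures
  )
  S4Vectors::metadata(out) <- md
  out
}

#' Log-normalize raw counts
#'
#' Scales each cell's counts to a common library size and log-transforms:
#' \deqn{y_{gc} = \ln(1 + n_{gc} \cdot s / N_c)}
#' with raw count \eqn{n_{gc}}, cell total \eqn{N_c} and scale factor
#' \eqn{s} (default 10,000). Zero counts stay exactly zero, so the sparsity
#' pattern is preserved. The natural logarithm is the default; `base`
#' rescales to another logarithm base.
#'
#' @param sce A SingleCellExperiment whose cells all have positive totals
#'   (run [qcFilter()] first).
#' @param scaleFactor Positive library-size target (default 10000).
#' @param base Logarithm base (default `exp(1)`).
#' @return The SingleCellExperiment with a sparse `logcounts` assay added.
#' @export
logNormalize <- function(sce, scaleFactor = 10000, base = exp(1)) {
  if (scaleFactor <= 0) stop("'scaleFactor' must be positive")
  counts <- methods::as(methods::as(
    SummarizedExperiment::assay(sce, "counts"), "generalMatrix"),
    "CsparseMatrix")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total count present; apply qcFilter() before ",
         "log-normalization")
  lc <- counts
  if (length(lc@x)) {
    percol <- rep.int(totals, diff(lc@p))
    lc@x <- log1p(lc@x * scaleFactor / percol) / log(base)
  }
  SummarizedExperiment::assay(sce, "logcounts") <- lc
  md <- S4Vectors::metadata(sce)
  md$logNormalize <- list(scaleFactor = scaleFactor, base = base)
  S4Vectors::metadata(sce) <- md
  sce
}

#' Rank genes by variance-stabilized variability
#'
#' Optional highly-variable-gene selection: per-gene counts are standardized
#' using a loess fit of log10(variance) on log10(mean) (span 0.3), values
#' clipped at \eqn{\sqrt{N}}, and genes ranked by the variance of the
#' standardized counts. No downstream stage requires this subset — coupling
#' and profiling operate on named gene sets — but it reproduces the common
#' preprocessing convention.
#'
#' @param sce A SingleCellExperiment with a `counts` assay.
#' @param nFeatures Number of top-variable genes to return (default 2000).
#' @return Character vector of gene names, most variable first.
#' @export
selectVariableGenes <- function(sce, nFeatures = 2000L) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  mu <- Matrix::rowMeans(counts)
  v <- Matrix::rowMeans(counts^2) * ncol(counts) / max(1, ncol(counts) - 1) -
    mu^2 * ncol(counts) / max(1, ncol(counts) - 1)
  ok <- v > 0 & mu > 0
  if (!any(ok)) return(character(0))
  fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.3,
                      degree = 2)
  sdExp <- sqrt(10^stats::predict(fit))
  clip <- sqrt(ncol(counts))
  dense <- as.matrix(counts[ok, , drop = FALSE])
  z <- (dense - mu[ok]) / sdExp
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  stdVar <- apply(z, 1, stats::var)
  names(sort(stdVar, decreasing = TRUE))[seq_len(min(nFeatures, sum(ok)))]
}
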