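#' @import methods
#' @importFrom stats pnorm psignrank pwilcox p.adjust rnbinom rlnorm rnorm
#'   runif sd setNames ave
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Canonical hippocampal cell-type order
#'
#' The display order used for hippocampal subclasses throughout the package:
#' non-neuronal types first (astrocytes, oligodendrocytes, endothelial cells,
#' microglia/perivascular macrophages), then GABAergic subtypes, then the
#' glutamatergic populations of the tri-synaptic circuit (DG, CA1-ProS, CA2,
#' CA3). Profiles and coupling tables fall back to lexicographic order when
#' group labels do not all belong to this set.
#'
#' @format A character vector of 13 subclass labels.
#' @export
hippocampalSubclasses <- c(
  "Astro", "Oligo", "Endo", "Micro-PVM",
  "Lamp5", "Vip", "Pvalb", "Sncg", "Sst",
  "DG", "CA1-ProS", "CA2", "CA3"
)

#' TypeProfile: per-cell-type expression profile
#'
#' Holds, for each gene and cell type, the average log-normalized expression
#' \eqn{x_{it}}, the percentage of cells with nonzero raw count
#' (percent-positive), the number of cells per group, and optionally the
#' row-standardized z-score of the averages.
#'
#' @slot x numeric matrix, genes x groups, average log-normalized expression.
#' @slot pctPos numeric matrix, genes x groups, percent-positive in [0, 100].
#' @slot nCells named integer vector of cells per group.
#' @slot z numeric matrix of row z-scores (0 x 0 until \code{zScores<-} or
#'   \code{scoreProfile()} fills it).
#' @slot groupKey character(1), the annotation column the profile was
#'   aggregated over (possibly a composite such as \code{"group.sex"}).
#'
#' @seealso [aggregateProfile()], [scoreProfile()], [couplingScore()]
#' @export
setClass("TypeProfile",
  representation(
    x = "matrix",
    pctPos = "matrix",
    nCells = "integer",
    z = "matrix",
    groupKey = "character"
  ),
  prototype(
    x = matrix(numeric(0), 0, 0),
    pctPos = matrix(numeric(0), 0, 0),
    nCells = integer(0),
    z = matrix(numeric(0), 0, 0),
    groupKey = "group"
  )
)

setValidity("TypeProfile", function(object) {
  msg <- character(0)
  if (!identical(dim(object@x), dim(object@pctPos)))
    msg <- c(msg, "'x' and 'pctPos' must have identical dimensions")
  if (ncol(object@x) != length(object@nCells))
    msg <- c(msg, "'nCells' must have one entry per group column")
  if (length(object@x) && any(object@x < 0))
    msg <- c(msg, "average log-normalized expression must be non-negative")
  if (length(object@pctPos) &&
      (any(object@pctPos < 0) || any(object@pctPos > 100)))
    msg <- c(msg, "'pctPos' must lie in [0, 100]")
  if (length(object@nCells) && any(object@nCells < 0L))
    msg <- c(msg, "'nCells' must be non-negative")
  if (length(object@z) && !identical(dim(object@z), dim(object@x)))
    msg <- c(msg, "'z', when filled, must match dim(x)")
  if (length(msg)) msg else TRUE
})

#' CouplingResult: coupling scores of receptors with a gene set
#'
#' Long-format records of the raw coupling score
#' \eqn{k_{ijt} = \log_{10}(x_{it} x_{jt})} and its min-max-normalized form
#' within a gene set, for one or more receptor genes across cell types.
#'
#' @slot records data.frame with columns \code{receptor}, \code{gene},
#'   \code{group}, \code{k}, \code{cNorm}, \code{set}.
#' @slot setName character(1), name of the gene set S.
#' @slot receptors character, the receptor genes j.
#' @slot epsilon numeric(1), the expression floor applied before log10.
#' @slot scope character(1), normalization scope (\code{"set_by_group_grid"}
#'   or \code{"per_group"}).
#'
#' @seealso [couplingScore()], [shortlistCoupling()], [couplingMatrix()]
#' @export
setClass("CouplingResult",
  representation(
    records = "data.frame",
    setName = "character",
    receptors = "character",
    epsilon = "numeric",
    scope = "character"
  )
)

setValidity("CouplingResult", function(object) {
  msg <- character(0)
  need <- c("receptor", "gene", "group", "k", "cNorm", "set")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  else {
    cn <- object@records$cNorm
    if (length(cn) && (any(cn < -1e-12) || any(cn > 1 + 1e-12)))
      msg <- c(msg, "cNorm must lie in [0, 1]")
    if (length(object@records$k) && any(!is.finite(object@records$k)))
      msg <- c(msg, "k must be finite (epsilon flooring should guarantee this)")
  }
  if (length(object@epsilon) != 1L || object@epsilon <= 0)
    msg <- c(msg, "epsilon must be a single positive number")
  if (length(msg)) msg else TRUE
})
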