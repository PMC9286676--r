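#' @rdname TypeProfile-accessors
#' @export
setGeneric("avgExpr", function(object) standardGeneric("avgExpr"))

#' @rdname TypeProfile-accessors
#' @export
setGeneric("pctPositive", function(object) standardGeneric("pctPositive"))

#' @rdname TypeProfile-accessors
#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))

#' @rdname TypeProfile-accessors
#' @export
setGeneric("zScores", function(object) standardGeneric("zScores"))

#' @rdname TypeProfile-accessors
#' @export
setGeneric("groupKey", function(object) standardGeneric("groupKey"))

#' @rdname CouplingResult-accessors
#' @export
setGeneric("couplingRecords", function(object) standardGeneric("couplingRecords"))

#' Accessors for TypeProfile objects
#'
#' \code{avgExpr()} returns the genes x groups matrix of average
#' log-normalized expression; \code{pctPositive()} the percent-positive
#' matrix (0-100); \code{cellCounts()} the named per-group cell counts;
#' \code{zScores()} the row-standardized averages (empty until
#' [scoreProfile()] is called); \code{groupKey()} the annotation column
#' that defined the groups.
#'
#' @param object A \linkS4class{TypeProfile}.
#' @return A matrix, integer vector, or character scalar as described.
#' @name TypeProfile-accessors
#' @aliases avgExpr pctPositive cellCounts zScores groupKey
#'   avgExpr,TypeProfile-method pctPositive,TypeProfile-method
#'   cellCounts,TypeProfile-method zScores,TypeProfile-method
#'   groupKey,TypeProfile-method
#' @examples
#' sce <- simulateCounts(simConfig(nGroups = 2, cellsPerGroup = 20,
#'                                 nGenes = 50, seed = 1))
#' sce <- logNormalize(sce)
#' pr <- aggregateProfile(sce)
#' dim(avgExpr(pr))
#' cellCounts(pr)
NULL

setMethod("avgExpr", "TypeProfile", function(object) object@x)
setMethod("pctPositive", "TypeProfile", function(object) object@pctPos)
setMethod("cellCounts", "TypeProfile", function(object) object@nCells)
setMethod("zScores", "TypeProfile", function(object) object@z)
setMethod("groupKey", "TypeProfile", function(object) object@groupKey)

setMethod("show", "TypeProfile", function(object) {
  cat("TypeProfile:", nrow(object@x), "genes x", ncol(object@x), "groups",
      sprintf("(grouped by '%s')\n", object@groupKey))
  cat(" groups:", paste(colnames(object@x), collapse = ", "), "\n")
  cat(" cells :", sum(object@nCells), "total\n")
  cat(" z     :", if (length(object@z)) "filled" else "not computed", "\n")
  invisible(NULL)
})

#' Accessors for CouplingResult objects
#'
#' \code{couplingRecords()} returns the long-format data.frame of raw
#' (\code{k}) and normalized (\code{cNorm}) coupling scores with one row per
#' (receptor, gene, group).
#'
#' @param object A \linkS4class{CouplingResult}.
#' @return A data.frame.
#' @name CouplingResult-accessors
#' @aliases couplingRecords couplingRecords,CouplingResult-method
NULL

setMethod("couplingRecords", "CouplingResult", function(object) object@records)

setMethod("show", "CouplingResult", function(object) {
  r <- object@records
  cat("CouplingResult: set '", object@setName, "' (",
      length(unique(r$gene)), " genes) x ",
      length(unique(r$group)), " groups\n", sep = "")
  cat(" receptors:", paste(object@receptors, collapse = ", "), "\n")
  cat(" scope    :", object@scope, " epsilon:", format(object@epsilon), "\n")
  cat(" records  :", nrow(r), "rows\n")
  invisible(NULL)
})
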