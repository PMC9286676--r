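.SOURCE_TYPES <- c("meta_transcriptomic", "inhouse_rnaseq", "chipseq")
.DIRECTIONS <- c("up", "down", "na")
.BINDINGS <- c("GR", "MR", "both", "none")

#' Validate an evidence table
#'
#' Checks the per-gene, per-study evidence schema: columns `gene`,
#' `source_type`, `study_id`, `direction`, `binding`; `source_type` one of
#' `meta_transcriptomic`, `inhouse_rnaseq`, `chipseq`; transcriptomic rows
#' must carry `direction` in `{up, down}`; ChIP-seq rows must carry
#' `direction = na` and a `binding` other than `none`; and
#' (gene, study_id, source_type) must be unique. Gene symbols are
#' whitespace-trimmed and matched case-sensitively.
#'
#' @param evidence data.frame to validate.
#' @return The validated (trimmed) data.frame, invisibly unchanged
#'   otherwise.
#' @export
validateEvidence <- function(evidence) {
  need <- c("gene", "source_type", "study_id", "direction", "binding")
  missing <- setdiff(need, names(evidence))
  if (length(missing))
    stop("evidence table lacks columns: ", paste(missing, collapse = ", "))
  evidence$gene <- trimws(evidence$gene)
  if (!nrow(evidence)) return(invisible(evidence))
  bad <- which(!evidence$source_type %in% .SOURCE_TYPES)
  if (length(bad))
    stop("invalid source_type '", evidence$source_type[bad[1]],
         "' at row ", bad[1])
  bad <- which(!evidence$direction %in% .DIRECTIONS)
  if (length(bad))
    stop("invalid direction '", evidence$direction[bad[1]],
         "' at row ", bad[1])
  bad <- which(!evidence$binding %in% .BINDINGS)
  if (length(bad))
    stop("invalid binding '", evidence$binding[bad[1]], "' at row ", bad[1])
  tx <- evidence$source_type != "chipseq"
  bad <- which(tx & !evidence$direction %in% c("up", "down"))
  if (length(bad))
    stop("transcriptomic row ", bad[1], " must have direction up/down")
  bad <- which(!tx & evidence$direction != "na")
  if (length(bad))
    stop("chipseq row ", bad[1], " must have direction 'na'")
  bad <- which(!tx & evidence$binding == "none")
  if (length(bad))
    stop("chipseq row ", bad[1], " must carry a binding annotation")
  key <- paste(evidence$gene, evidence$study_id, evidence$source_type,
               sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad))
    stop("duplicate (gene, study_id, source_type) at row ", bad[1], ": ",
         evidence$gene[bad[1]], " / ", evidence$study_id[bad[1]])
  invisible(evidence)
}

#' Read an evidence table from TSV
#'
#' @param path Tab-separated file with header
#'   (gene, source_type, study_id, direction, binding).
#' @return The validated evidence data.frame.
#' @seealso [validateEvidence()], [applyConsensus()]
#' @export
readEvidence <- function(path) {
  ev <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  validateEvidence(ev)
  ev$gene <- trimws(ev$gene)
  ev
}

#' Receptor-binding class of a gene
#'
#' Union over the gene's ChIP-seq rows: GR-only annotations give `"GR"`,
#' MR-only `"MR"`, any mixture (or an explicit `both` row) `"both"`, and no
#' ChIP-seq evidence `"none"`.
#'
#' @param gene Gene symbol.
#' @param evidence Validated evidence table.
#' @return One of `"GR"`, `"MR"`, `"both"`, `"none"`.
#' @export
classifyBinding <- function(gene, evidence) {
  rows <- evidence[evidence$gene == gene &
                   evidence$source_type == "chipseq", , drop = FALSE]
  if (!nrow(rows)) return("none")
  b <- unique(rows$binding)
  if ("both" %in% b || all(c("GR", "MR") %in% b)) return("both")
  if ("GR" %in% b) return("GR")
  "MR"
}

#' Direction consistency of a gene's transcriptomic reports
#'
#' A gene is direction-consistent when all its transcriptomic rows
#' (meta-analysis and in-house combined) report the same regulation
#' direction. A gene with no transcriptomic rows is inconsistent by
#' definition (undefined direction).
#'
#' @param gene Gene symbol.
#' @param evidence Validated evidence table.
#' @return List with `consistent` (logical) and `direction` (`"up"`,
#'   `"down"`, or `NA`).
#' @export
directionConsistent <- function(gene, evidence) {
  rows <- evidence[evidence$gene == gene &
                   evidence$source_type != "chipseq", , drop = FALSE]
  if (!nrow(rows))
    return(list(consistent = FALSE, direction = NA_character_))
  d <- unique(rows$direction)
  if (length(d) == 1L) list(consistent = TRUE, direction = d)
  else list(consistent = FALSE, direction = NA_character_)
}

#' Per-gene consensus criteria evaluation
#'
#' Evaluates, for every gene in the table, the four target-gene criteria —
#' (1) reported in the published meta-analysis, (2) responsive in the
#' in-house RNA-seq, (3) direction-consistent across all reporting
#' transcriptomic studies, (4) GR and/or MR ChIP-seq binding — plus the
#' minimum-reporting-studies rule (distinct transcriptomic study ids,
#' meta-analysis and in-house combined; ChIP-seq studies never count).
#'
#' @param evidence Validated evidence table.
#' @param minReportingStudies Minimum distinct transcriptomic studies
#'   (default 3); set to 1 to disable the extra rule.
#' @param requireInhouse Enforce criterion 2 (default TRUE).
#' @return data.frame with one row per gene: criteria flags
#'   (`crit_meta`, `crit_inhouse`, `crit_direction`, `crit_binding`,
#'   `crit_min_studies`), `direction`, `binding_class`,
#'   `n_reporting_studies`, `studies`, and `call` (all enabled criteria
#'   true).
#' @seealso [applyConsensus()]
#' @export
consensusCriteria <- function(evidence, minReportingStudies = 3L,
                              requireInhouse = TRUE) {
  evidence <- validateEvidence(evidence)
  genes <- sort(unique(evidence$gene))
  if (!length(genes)) {
    return(data.frame(
      gene = character(0), direction = character(0),
      binding_class = character(0), n_reporting_studies = integer(0),
      crit_meta = logical(0), crit_inhouse = logical(0),
      crit_direction = logical(0), crit_binding = logical(0),
      crit_min_studies = logical(0), call = logical(0),
      studies = character(0), stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(genes, function(g) {
    ev <- evidence[evidence$gene == g, , drop = FALSE]
    tx <- ev[ev$source_type != "chipseq", , drop = FALSE]
    dc <- directionConsistent(g, ev)
    binding <- classifyBinding(g, ev)
    nStudies <- length(unique(tx$study_id))
    data.frame(
      gene = g,
      direction = if (dc$consistent) dc$direction else NA_character_,
      binding_class = binding,
      n_reporting_studies = nStudies,
      crit_meta = any(ev$source_type == "meta_transcriptomic"),
      crit_inhouse = if (requireInhouse)
        any(ev$source_type == "inhouse_rnaseq") else TRUE,
      crit_direction = dc$consistent,
      crit_binding = binding != "none",
      crit_min_studies = nStudies >= minReportingStudies,
      studies = paste(sort(unique(tx$study_id)), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$call <- out$crit_meta & out$crit_inhouse & out$crit_direction &
    out$crit_binding & out$crit_min_studies
  out[, c("gene", "direction", "binding_class", "n_reporting_studies",
          "crit_meta", "crit_inhouse", "crit_direction", "crit_binding",
          "crit_min_studies", "call", "studies")]
}

#' Call consensus target genes
#'
#' Applies the multi-evidence consensus filter: a gene is called a target
#' iff it is reported in the meta-analysis, responsive in the in-house
#' RNA-seq (when `requireInhouse`), direction-consistent across all
#' reporting studies, carries GR/MR binding evidence, and is reported by at
#' least `minReportingStudies` distinct transcriptomic studies. The result
#' carries full per-criterion provenance, sorted by gene symbol.
#'
#' @inheritParams consensusCriteria
#' @return data.frame of calls (rows of [consensusCriteria()] output where
#'   every enabled criterion holds).
#' @export
#' @examples
#' sim <- simulateEvidence(evidenceSimConfig(nTrueTargets = 3, seed = 2))
#' applyConsensus(sim$evidence)$gene
applyConsensus <- function(evidence, minReportingStudies = 3L,
                           requireInhouse = TRUE) {
  crit <- consensusCriteria(evidence, minReportingStudies, requireInhouse)
  out <- crit[crit$call, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize an evidence table and its consensus calls
#'
#' Tallies the evidence-integration funnel: the size of the union gene
#' list, genes per ChIP-seq binding class, genes reported in the
#' meta-analysis, genes responsive in the in-house RNA-seq, the
#' direction-consistent intersection of both transcriptomic sources, and
#' the final calls broken down by direction and binding class.
#'
#' @param evidence Validated evidence table.
#' @param calls Optional precomputed [applyConsensus()] output; recomputed
#'   with the given parameters when NULL.
#' @inheritParams consensusCriteria
#' @return Named list of integer counts.
#' @export
summarizeEvidence <- function(evidence, calls = NULL,
                              minReportingStudies = 3L,
                              requireInhouse = TRUE) {
  crit <- consensusCriteria(evidence, minReportingStudies, requireInhouse)
  if (is.null(calls)) calls <- crit[crit$call, , drop = FALSE]
  list(
    n_genes_union = nrow(crit),
    n_binding_gr = sum(crit$binding_class == "GR"),
    n_binding_mr = sum(crit$binding_class == "MR"),
    n_binding_both = sum(crit$binding_class == "both"),
    n_meta_reported = sum(crit$crit_meta),
    n_inhouse_responsive = sum(vapply(
      crit$gene, function(g)
        any(evidence$gene == g & evidence$source_type == "inhouse_rnaseq"),
      logical(1))),
    n_consistent_intersection = sum(crit$crit_meta &
      vapply(crit$gene, function(g)
        any(evidence$gene == g & evidence$source_type == "inhouse_rnaseq"),
        logical(1)) & crit$crit_direction),
    n_calls = nrow(calls),
    n_calls_up = sum(calls$direction == "up"),
    n_calls_down = sum(calls$direction == "down"),
    n_calls_gr = sum(calls$binding_class == "GR"),
    n_calls_mr = sum(calls$binding_class == "MR"),
    n_calls_both = sum(calls$binding_class == "both")
  )
}
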