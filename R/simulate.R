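#' Configuration for the labeled scRNA-seq count simulator
#'
#' Builds and validates the parameter set for [simulateCounts()]. The
#' simulator emulates a droplet-style experiment over labeled cell types:
#' negative-binomial counts (variance \eqn{\mu + \mu^2/\phi} with size
#' \eqn{\phi}) around per-gene base means, multiplied per cell by a
#' log-normal library-size factor, with optional receptor-specific
#' per-group expression patterns and planted co-expressed gene pairs.
#'
#' @param nGroups Number of cell types. When 13 (the default), groups are
#'   named after the hippocampal subclasses in [hippocampalSubclasses];
#'   otherwise `Group01`, `Group02`, ...
#' @param cellsPerGroup Integer vector of cells per group (recycled to
#'   `nGroups`). Default 200.
#' @param nGenes Number of genes, including the designated receptor genes.
#' @param baseMean Scale of the negative-binomial mean per gene (counts per
#'   cell at library factor 1). Default 0.2, a typical droplet depth.
#' @param dispersion Negative-binomial size parameter \eqn{\phi} (smaller =
#'   more overdispersed). Default 1.
#' @param libsizeSigma Standard deviation (log scale) of the per-cell
#'   library-size factor; factors are drawn log-normal with expectation 1.
#'   Default 0.3.
#' @param geneMeanSigma Log-scale spread of per-gene base means around
#'   `baseMean`, giving a realistic skewed mean-expression distribution.
#'   Default 1. Set to 0 for identical gene means.
#' @param plantedPairs List of planted co-expression signals, each a list
#'   with elements `geneA`, `geneB` (gene names), `group` (group name) and
#'   `fold` (> 1): both genes have their mean multiplied by `fold` in that
#'   group only.
#' @param receptorProfile Named list mapping receptor gene names to a
#'   per-group multiplier vector of length `nGroups`. The defaults plant
#'   `Nr3c1` (broadly expressed, highest in non-neuronal types) and `Nr3c2`
#'   (highest in glutamatergic neurons), mirroring the corticosteroid
#'   receptor pattern in hippocampus. Receptor base means are fixed at
#'   `baseMean` before the multiplier (no log-normal draw), so their
#'   expected profile is known exactly.
#' @param femaleFraction Probability a cell is annotated female. Default 0.5.
#' @param seed Integer seed; the same configuration yields byte-identical
#'   output.
#'
#' @return A validated list of class `SimConfig`.
#' @seealso [simulateCounts()], [writeFixture()]
#' @export
#' @examples
#' cfg <- simConfig(nGroups = 2, cellsPerGroup = c(5, 5), nGenes = 10, seed = 1)
#' sce <- simulateCounts(cfg)
#' dim(sce)
simConfig <- function(nGroups = 13L,
                      cellsPerGroup = 200L,
                      nGenes = 2000L,
                      baseMean = 0.2,
                      dispersion = 1,
                      libsizeSigma = 0.3,
                      geneMeanSigma = 1,
                      plantedPairs = list(),
                      receptorProfile = NULL,
                      femaleFraction = 0.5,
                      seed = 1L) {
  nGroups <- as.integer(nGroups)
  if (nGroups < 1L) stop("'nGroups' must be a positive integer")
  cellsPerGroup <- as.integer(rep_len(cellsPerGroup, nGroups))
  if (any(cellsPerGroup < 0L)) stop("'cellsPerGroup' must be non-negative")
  nGenes <- as.integer(nGenes)
  if (nGenes < 1L) stop("'nGenes' must be a positive integer")
  for (p in c(baseMean = baseMean, dispersion = dispersion)) {
    if (!is.finite(p) || p <= 0)
      stop("'baseMean' and 'dispersion' must be strictly positive")
  }
  if (libsizeSigma < 0) stop("'libsizeSigma' must be non-negative")
  if (geneMeanSigma < 0) stop("'geneMeanSigma' must be non-negative")
  groupNames <- if (nGroups == length(hippocampalSubclasses)) {
    hippocampalSubclasses
  } else {
    sprintf("Group%02d", seq_len(nGroups))
  }
  if (is.null(receptorProfile)) {
    receptorProfile <- .defaultReceptorProfile(groupNames)
  }
  if (length(receptorProfile)) {
    if (is.null(names(receptorProfile)) || any(names(receptorProfile) == ""))
      stop("'receptorProfile' must be a named list of multiplier vectors")
    receptorProfile <- lapply(receptorProfile, function(m) {
      m <- rep_len(as.numeric(m), nGroups)
      if (any(!is.finite(m)) || any(m < 0))
        stop("receptor multipliers must be finite and non-negative")
      m
    })
    if (length(receptorProfile) > nGenes)
      stop("more receptor genes than 'nGenes'")
  }
  for (pp in plantedPairs) {
    if (!all(c("geneA", "geneB", "group", "fold") %in% names(pp)))
      stop("each planted pair needs 'geneA', 'geneB', 'group', 'fold'")
    if (!pp$group %in% groupNames)
      stop("planted pair group '", pp$group, "' is not a simulated group")
    if (pp$fold <= 1) stop("planted 'fold' must exceed 1")
  }
  structure(list(
    nGroups = nGroups, cellsPerGroup = cellsPerGroup, nGenes = nGenes,
    baseMean = baseMean, dispersion = dispersion,
    libsizeSigma = libsizeSigma, geneMeanSigma = geneMeanSigma,
    plantedPairs = plantedPairs, receptorProfile = receptorProfile,
    femaleFraction = femaleFraction,
    groupNames = groupNames, seed = as.integer(seed)
  ), class = "SimConfig")
}

# Default corticosteroid-receptor pattern: Nr3c1 broad with a non-neuronal
# bias, Nr3c2 enriched in glutamatergic neurons; generic fallback for
# non-hippocampal group names.
.defaultReceptorProfile <- function(groupNames) {
  n <- length(groupNames)
  glia <- c("Astro", "Oligo", "Endo", "Micro-PVM")
  glut <- c("DG", "CA1-ProS", "CA2", "CA3")
  if (all(c(glia, glut) %in% groupNames)) {
    nr3c1 <- setNames(rep(2, n), groupNames)
    nr3c1[glia] <- 5
    nr3c2 <- setNames(rep(1.5, n), groupNames)
    nr3c2[glut] <- 6
    nr3c2[glia] <- 0.5
  } else {
    half <- seq_len(ceiling(n / 2))
    nr3c1 <- rep(1.5, n); nr3c1[half] <- 4
    nr3c2 <- rep(4, n);   nr3c2[half] <- 1
    names(nr3c1) <- names(nr3c2) <- groupNames
  }
  list(Nr3c1 = unname(nr3c1), Nr3c2 = unname(nr3c2))
}

#' Simulate a labeled single-cell count matrix
#'
#' Draws a sparse genes x cells matrix of negative-binomial counts under the
#' configuration from [simConfig()], together with a per-cell annotation
#' table (group, sex, region, subcluster). The expected mean matrix
#' (genes x groups, before the library-size factor) is stored in
#' `metadata(sce)$mu`, so downstream recovery tests have an exact ground
#' truth.
#'
#' @param config A `SimConfig` from [simConfig()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay, `rowData` columns `gene_id`/`symbol`, `colData` columns
#'   `cell_id`/`group`/`sex`/`region`/`subcluster`, and the configuration,
#'   expected means and library factors in `metadata()`.
#' @export
simulateCounts <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  set.seed(config$seed)
  nGenes <- config$nGenes
  nCells <- sum(config$cellsPerGroup)
  groups <- rep(config$groupNames, times = config$cellsPerGroup)

  receptors <- names(config$receptorProfile)
  symbols <- sprintf("Gene%04d", seq_len(nGenes))
  if (length(receptors)) symbols[seq_along(receptors)] <- receptors
  geneIds <- sprintf("SIM%05d", seq_len(nGenes))

  # per-gene base means: log-normal spread around baseMean, mean-one factor;
  # receptor genes sit exactly at baseMean so their planted profile is exact
  meanFactors <- if (config$geneMeanSigma > 0) {
    exp(rnorm(nGenes, -config$geneMeanSigma^2 / 2, config$geneMeanSigma))
  } else rep(1, nGenes)
  if (length(receptors)) meanFactors[seq_along(receptors)] <- 1

  mu <- matrix(config$baseMean * meanFactors, nGenes, config$nGroups)
  dimnames(mu) <- list(symbols, config$groupNames)
  for (r in seq_along(receptors)) {
    mu[receptors[r], ] <- config$baseMean * config$receptorProfile[[r]]
  }
  for (pp in config$plantedPairs) {
    for (g in c(pp$geneA, pp$geneB)) {
      if (!g %in% symbols)
        stop("planted pair gene '", g, "' is not among the simulated genes")
      mu[g, pp$group] <- mu[g, pp$group] * pp$fold
    }
  }

  libFactors <- if (config$libsizeSigma > 0) {
    rlnorm(nCells, -config$libsizeSigma^2 / 2, config$libsizeSigma)
  } else rep(1, nCells)

  counts <- matrix(0L, nGenes, nCells)
  for (c in seq_len(nCells)) {
    counts[, c] <- rnbinom(nGenes, mu = mu[, groups[c]] * libFactors[c],
                           size = config$dispersion)
  }
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  cellIds <- sprintf("cell%05d", seq_len(nCells))
  dimnames(counts) <- list(symbols, cellIds)

  sex <- ifelse(runif(nCells) < config$femaleFraction, "F", "M")
  coldata <- S4Vectors::DataFrame(
    cell_id = cellIds,
    group = groups,
    sex = sex,
    region = rep("HIP", nCells),
    subcluster = paste0(groups, "_1"),
    row.names = cellIds
  )
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_id = geneIds, symbol = symbols,
                                   row.names = symbols),
    colData = coldata
  )
  S4Vectors::metadata(sce) <- list(simConfig = config, mu = mu,
                                   libFactors = libFactors)
  sce
}

#' Configuration for the evidence-table simulator
#'
#' Parameters for [simulateEvidence()], which generates a per-gene,
#' per-study evidence table (transcriptomic regulation directions plus
#' ChIP-seq receptor-binding annotations) with known consensus truth: a set
#' of true target genes passing all four consensus criteria, and decoy genes
#' each engineered to violate exactly one criterion.
#'
#' The defaults mirror the composition of the published hippocampal GR/MR
#' evidence synthesis: 19 true targets split 15 up- / 4 down-regulated with
#' binding classes 14 GR / 1 MR / 4 both, drawn against a 17-study
#' meta-analysis plus a single in-house RNA-seq study.
#'
#' @param nTrueTargets Number of genes passing every criterion.
#' @param decoysPerFailureMode Number of decoy genes per failure mode. The
#'   four modes are: absent from the meta-analysis, absent from the in-house
#'   RNA-seq, direction-inconsistent across studies, and no receptor-binding
#'   annotation.
#' @param nStudiesMeta Number of distinct meta-analysis study ids available.
#' @param upFraction Fraction of true targets assigned direction `up`
#'   (largest-remainder rounding). Default 15/19.
#' @param bindingWeights Named weights for binding classes `GR`, `MR`,
#'   `both` among true targets, apportioned by largest remainder.
#'   Default `c(GR = 14, MR = 1, both = 4)`.
#' @param seed Integer seed; identical configurations give identical tables.
#' @return A validated list of class `EvidenceSimConfig`.
#' @seealso [simulateEvidence()], [applyConsensus()]
#' @export
evidenceSimConfig <- function(nTrueTargets = 19L,
                              decoysPerFailureMode = 1L,
                              nStudiesMeta = 17L,
                              upFraction = 15 / 19,
                              bindingWeights = c(GR = 14, MR = 1, both = 4),
                              seed = 1L) {
  nTrueTargets <- as.integer(nTrueTargets)
  decoysPerFailureMode <- as.integer(decoysPerFailureMode)
  nStudiesMeta <- as.integer(nStudiesMeta)
  if (nTrueTargets < 0L) stop("'nTrueTargets' must be >= 0")
  if (decoysPerFailureMode < 0L) stop("'decoysPerFailureMode' must be >= 0")
  if (nStudiesMeta < 2L) stop("'nStudiesMeta' must be >= 2")
  if (upFraction < 0 || upFraction > 1) stop("'upFraction' must be in [0, 1]")
  if (!all(c("GR", "MR", "both") %in% names(bindingWeights)))
    stop("'bindingWeights' must name GR, MR and both")
  structure(list(
    nTrueTargets = nTrueTargets,
    decoysPerFailureMode = decoysPerFailureMode,
    nStudiesMeta = nStudiesMeta,
    upFraction = upFraction,
    bindingWeights = bindingWeights[c("GR", "MR", "both")],
    seed = as.integer(seed)
  ), class = "EvidenceSimConfig")
}

# largest-remainder apportionment of n into named integer shares
.apportion <- function(n, weights) {
  if (n == 0L) return(setNames(integer(length(weights)), names(weights)))
  w <- weights / sum(weights)
  raw <- w * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(weights))
}

#' Simulate an evidence table with known consensus truth
#'
#' Generates rows of (gene, source_type, study_id, direction, binding)
#' evidence. True targets carry 2+ consistent meta-analysis reports, a
#' consistent in-house RNA-seq report (hence at least three reporting
#' transcriptomic studies) and a ChIP-seq binding annotation. Each decoy
#' violates exactly one of the four consensus criteria; note that a gene
#' absent from the meta-analysis necessarily also falls below the
#' three-reporting-studies rule, since only one in-house study exists.
#'
#' @param config An `EvidenceSimConfig` from [evidenceSimConfig()].
#' @return A list with elements `evidence` (the validated evidence
#'   data.frame) and `truth` (data.frame of gene, label, direction,
#'   bindingClass; label is `"pass"` or `"fail:<mode>"`).
#' @export
simulateEvidence <- function(config) {
  if (!inherits(config, "EvidenceSimConfig"))
    config <- do.call(evidenceSimConfig, config)
  set.seed(config$seed)
  metaStudies <- sprintf("meta%02d", seq_len(config$nStudiesMeta))
  inhouseStudy <- "inhouse_rnaseq_hc"

  rows <- list()
  truth <- list()
  addRow <- function(gene, src, study, direction, binding) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, source_type = src, study_id = study,
      direction = direction, binding = binding,
      stringsAsFactors = FALSE
    )
  }
  addChip <- function(gene, class) {
    if (class %in% c("GR", "both"))
      addRow(gene, "chipseq", "chip_gr_hc", "na", "GR")
    if (class %in% c("MR", "both"))
      addRow(gene, "chipseq", "chip_mr_hc", "na", "MR")
  }
  addTranscriptomic <- function(gene, nMeta, direction, inhouse = TRUE,
                                inhouseDirection = direction) {
    for (s in sample(metaStudies, nMeta))
      addRow(gene, "meta_transcriptomic", s, direction, "none")
    if (inhouse)
      addRow(gene, "inhouse_rnaseq", inhouseStudy, inhouseDirection, "none")
  }

  n <- config$nTrueTargets
  if (n > 0L) {
    nUp <- as.integer(round(config$upFraction * n))
    directions <- c(rep("up", nUp), rep("down", n - nUp))
    bindingN <- .apportion(n, config$bindingWeights)
    bindings <- rep(names(bindingN), times = bindingN)
    for (i in seq_len(n)) {
      gene <- sprintf("Tgt%03d", i)
      nMeta <- sample(2:min(6L, config$nStudiesMeta), 1L)
      addTranscriptomic(gene, nMeta, directions[i])
      addChip(gene, bindings[i])
      truth[[length(truth) + 1L]] <- data.frame(
        gene = gene, label = "pass", direction = directions[i],
        bindingClass = bindings[i], stringsAsFactors = FALSE
      )
    }
  }

  for (d in seq_len(config$decoysPerFailureMode)) {
    g <- sprintf("DecoyMeta%02d", d)   # fails: absent from meta-analysis
    addTranscriptomic(g, 0L, "up")
    addChip(g, "GR")
    truth[[length(truth) + 1L]] <- data.frame(
      gene = g, label = "fail:no_meta", direction = "up",
      bindingClass = "GR", stringsAsFactors = FALSE
    )

    g <- sprintf("DecoyInhouse%02d", d)  # fails: absent from in-house RNA-seq
    addTranscriptomic(g, 3L, "down", inhouse = FALSE)
    addChip(g, "GR")
    truth[[length(truth) + 1L]] <- data.frame(
      gene = g, label = "fail:no_inhouse", direction = "down",
      bindingClass = "GR", stringsAsFactors = FALSE
    )

    g <- sprintf("DecoyDirection%02d", d)  # fails: inconsistent direction
    s <- sample(metaStudies, 3L)
    addRow(g, "meta_transcriptomic", s[1L], "up", "none")
    addRow(g, "meta_transcriptomic", s[2L], "up", "none")
    addRow(g, "meta_transcriptomic", s[3L], "down", "none")
    addRow(g, "inhouse_rnaseq", inhouseStudy, "up", "none")
    addChip(g, "both")
    truth[[length(truth) + 1L]] <- data.frame(
      gene = g, label = "fail:inconsistent", direction = NA_character_,
      bindingClass = "both", stringsAsFactors = FALSE
    )

    g <- sprintf("DecoyBinding%02d", d)  # fails: no ChIP-seq annotation
    addTranscriptomic(g, 3L, "up")
    truth[[length(truth) + 1L]] <- data.frame(
      gene = g, label = "fail:no_binding", direction = "up",
      bindingClass = "none", stringsAsFactors = FALSE
    )
  }

  evidence <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), source_type = character(0),
               study_id = character(0), direction = character(0),
               binding = character(0), stringsAsFactors = FALSE)
  rownames(evidence) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene = character(0), label = character(0),
               direction = character(0), bindingClass = character(0),
               stringsAsFactors = FALSE)
  validateEvidence(evidence)
  list(evidence = evidence, truth = truth)
}
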