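#' Assemble or read a pipeline configuration
#'
#' A pipeline configuration bundles every stage parameter: input paths (or
#' a simulation request), QC thresholds, the normalization scale factor,
#' receptors, named gene sets, an evidence table path, coupling and marker
#' parameters, and a seed. `pipelineConfig()` validates a list;
#' `readPipelineConfig()` loads one from YAML.
#'
#' @param ... Named parameters overriding the defaults, or a single list.
#'   Recognized entries: `mtx`, `features`, `barcodes`, `annotation`
#'   (input file paths) or `simulate` (a list passed to [simConfig()]);
#'   `keepGroups`; `minCells`, `minFeatures`, `scaleFactor`; `receptors`;
#'   `geneSets` (named list of symbol vectors, or paths to gene-set TSVs);
#'   `evidence` (path or data.frame); `epsilon`, `scope`, `threshold`,
#'   `rule`; `minReportingStudies`, `requireInhouse`; `markers` (logical),
#'   `minPct`, `logfcThreshold`; `seed`.
#' @return A validated list of class `PipelineConfig`.
#' @seealso [runPipeline()]
#' @export
pipelineConfig <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args)))
    args <- args[[1]]
  cfg <- list(
    mtx = NULL, features = NULL, barcodes = NULL, annotation = NULL,
    simulate = NULL, keepGroups = NULL,
    minCells = 1L, minFeatures = 100L, scaleFactor = 10000,
    receptors = c("Nr3c1", "Nr3c2"), geneSets = list(),
    evidence = NULL, epsilon = 1e-6, scope = "set_by_group_grid",
    threshold = 0.6, rule = "either",
    minReportingStudies = 3L, requireInhouse = TRUE,
    markers = FALSE, minPct = 0.1, logfcThreshold = 0.25,
    seed = 1L
  )
  unknown <- setdiff(names(args), names(cfg))
  if (length(unknown))
    stop("unknown pipeline parameters: ", paste(unknown, collapse = ", "))
  cfg[names(args)] <- args
  haveFiles <- !is.null(cfg$mtx)
  if (!haveFiles && is.null(cfg$simulate))
    stop("config needs either input paths ('mtx', 'features', 'barcodes', ",
         "'annotation') or a 'simulate' block")
  if (haveFiles) {
    for (f in c("features", "barcodes", "annotation")) {
      if (is.null(cfg[[f]])) stop("input path missing: ", f)
    }
  }
  if (!cfg$scope %in% c("set_by_group_grid", "per_group"))
    stop("invalid 'scope': ", cfg$scope)
  if (!cfg$rule %in% c("either", "both"))
    stop("invalid 'rule': ", cfg$rule)
  if (cfg$threshold < 0 || cfg$threshold > 1)
    stop("'threshold' must lie in [0, 1]")
  structure(cfg, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  pipelineConfig(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes load/simulate, subset, QC, log-normalization, profiling,
#' coupling per gene set, shortlist, consensus target calling, and
#' (optionally) one-vs-rest markers, writing every result table plus a
#' manifest of parameters into `outDir`. Stage progress goes to `message()`;
#' output files contain no timestamps, so identical configurations and
#' seeds produce byte-identical bundles.
#'
#' @param config A `PipelineConfig` (or list / YAML path coercible to one).
#' @param outDir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results (`sce`, `profile`,
#'   `coupling`, `shortlists`, `calls`, `summary`, `markers`) and the
#'   manifest of written files.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- readPipelineConfig(config)
  if (!inherits(config, "PipelineConfig"))
    config <- pipelineConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  written <- character(0)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sce <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      if (!inherits(sim, "SimConfig")) {
        if (is.null(sim$seed)) sim$seed <- config$seed
        sim <- do.call(simConfig, sim)
      }
      simulateCounts(sim)
    } else {
      loadDataset(config$mtx, config$features, config$barcodes,
                  config$annotation)
    }
  })
  if (!is.null(config$keepGroups))
    sce <- stage("subset", subsetCells(sce, config$keepGroups))
  sce <- stage("qc", qcFilter(sce, config$minCells, config$minFeatures))
  sce <- stage("normalize", logNormalize(sce, config$scaleFactor))
  profile <- stage("profile", scoreProfile(aggregateProfile(sce)))

  pt <- profileTable(profile)
  f <- file.path(outDir, "profile_long.tsv")
  write.table(pt, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)

  geneSets <- config$geneSets
  if (length(geneSets)) {
    geneSets <- lapply(geneSets, function(s) {
      if (is.character(s) && length(s) == 1L && file.exists(s)) readGeneSet(s)
      else s
    })
    if (is.null(names(geneSets)))
      names(geneSets) <- sprintf("set%02d", seq_along(geneSets))
  }
  couplings <- list(); shortlists <- list()
  for (setName in names(geneSets)) {
    res <- stage(paste0("couple:", setName), couplingScore(
      profile, receptors = config$receptors, geneSet = geneSets[[setName]],
      setName = setName, epsilon = config$epsilon, scope = config$scope
    ))
    couplings[[setName]] <- res
    f <- file.path(outDir, paste0("coupling_", setName, ".tsv"))
    writeCouplingTable(res, f)
    written <- c(written, f)
    sl <- shortlistCoupling(res, config$threshold, config$rule)
    shortlists[[setName]] <- sl
    f <- file.path(outDir, paste0("shortlist_", setName, ".tsv"))
    write.table(sl, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }

  calls <- NULL; ev <- NULL; evSummary <- NULL
  if (!is.null(config$evidence)) {
    ev <- stage("evidence", {
      if (is.character(config$evidence)) readEvidence(config$evidence)
      else validateEvidence(config$evidence)
    })
    calls <- stage("consensus", applyConsensus(
      ev, config$minReportingStudies, config$requireInhouse))
    f <- file.path(outDir, "consensus_calls.tsv")
    write.table(calls, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
    evSummary <- summarizeEvidence(ev, calls, config$minReportingStudies,
                                   config$requireInhouse)
    f <- file.path(outDir, "evidence_summary.tsv")
    write.table(
      data.frame(metric = names(evSummary),
                 value = unlist(evSummary, use.names = FALSE)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }

  markers <- NULL
  if (isTRUE(config$markers)) {
    markers <- stage("markers", findGroupMarkers(
      sce, minPct = config$minPct, logfcThreshold = config$logfcThreshold))
    f <- file.path(outDir, "markers.tsv")
    write.table(markers, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }

  manifest <- list(
    package = "scCoupling",
    version = as.character(packageVersion("scCoupling")),
    parameters = unclass(config)[!vapply(config, is.null, TRUE)],
    files = basename(written)
  )
  manifest$parameters$simulate <-
    if (!is.null(config$simulate)) unclass(manifest$parameters$simulate)
  manifest$parameters$evidence <-
    if (is.character(config$evidence)) config$evidence else
      if (!is.null(config$evidence)) "<in-memory>"
  f <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(manifest, f)
  written <- c(written, f)

  invisible(list(sce = sce, profile = profile, coupling = couplings,
                 shortlists = shortlists, calls = calls,
                 summary = evSummary, markers = markers,
                 files = written))
}
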