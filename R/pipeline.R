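## End-to-end orchestration with reproducible configuration and a manifest.

#' Run the full thresholding pipeline
#'
#' Orchestrates every stage: read inputs, map genes to enzymes, bin and
#' cluster the profiles (selecting the cluster count by core-list stability
#' when \code{nClusters} is not given), resolve cluster-specific thresholds,
#' derive core reaction sets under the requested method, tailor the
#' model-extraction inputs, and (when a housekeeping reference is supplied)
#' evaluate coverage and enrichment. Every artifact plus a provenance
#' manifest is written to \code{outDir}.
#'
#' All stages are deterministic, so re-running with the same configuration
#' and inputs reproduces the outputs exactly.
#'
#' @param expression genes-by-contexts matrix, or path to a delimited file
#'   ([readExpressionMatrix()]).
#' @param model a [ReactionCatalog-class], or path to an SBML/JSON model
#'   ([readMetabolicModel()]).
#' @param outDir output directory (created if needed).
#' @param method core thresholding method: \code{"standep"},
#'   \code{"global"}, \code{"localT1"} or \code{"localT2"}.
#' @param nClusters cluster count N; if NULL, selected via
#'   [selectClusterCount()] over \code{nRange}.
#' @param nRange range scanned when selecting N (default c(2, 10)).
#' @param nBins,distance,linkage clustering parameters.
#' @param jaccardCut stability cut for N selection.
#' @param topPercentile,lowerTopPercentile,upperTopPercentile baseline
#'   method percentiles.
#' @param localT1Variant \code{"methods"} or \code{"results"}, see
#'   [localT1Core()].
#' @param band MBA band half-width.
#' @param protected reaction ids (or path to a one-id-per-line file) always
#'   added to core sets.
#' @param hkReactions optional housekeeping reaction ids (or path) for
#'   evaluation.
#' @param missingGenePolicy see [computeEnzymeExpression()].
#' @param verbose print per-stage progress and cluster diagnostics.
#' @return invisibly, a list with every intermediate object
#'   (\code{enzExpr}, \code{clustering}, \code{thresholds}, \code{core},
#'   \code{mem}, \code{evaluation}, \code{selection}, \code{config}).
#' @export
runPipeline <- function(expression, model, outDir,
                        method = c("standep", "global", "localT1", "localT2"),
                        nClusters = NULL, nRange = c(2L, 10L), nBins = 60L,
                        distance = "euclidean", linkage = "complete",
                        jaccardCut = 0.90, topPercentile = 25,
                        lowerTopPercentile = 75, upperTopPercentile = 25,
                        localT1Variant = c("methods", "results"),
                        band = 0.10, protected = character(),
                        hkReactions = NULL,
                        missingGenePolicy = c("drop", "zero"),
                        verbose = TRUE) {
  method <- match.arg(method)
  localT1Variant <- match.arg(localT1Variant)
  missingGenePolicy <- match.arg(missingGenePolicy)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  expr <- stage("read_expression",
                if (is.character(expression)) readExpressionMatrix(expression)
                else expression)
  catalog <- stage("read_model",
                   if (is.character(model)) readMetabolicModel(model)
                   else model)
  if (is.character(protected) && length(protected) == 1L &&
      file.exists(protected))
    protected <- readLines(protected)
  if (is.character(hkReactions) && length(hkReactions) == 1L &&
      file.exists(hkReactions))
    hkReactions <- readLines(hkReactions)

  say("mapping ", nrow(expr), " genes onto ",
      length(enzymeIds(catalog)), " enzymes")
  enzExpr <- stage("enzyme_expression",
                   computeEnzymeExpression(expr, catalog,
                                           missingGenePolicy =
                                             missingGenePolicy))
  writeEnzymeExpression(enzExpr, file.path(outDir, "enzyme_expression.tsv"))

  selection <- NULL
  clustering <- thresholds <- NULL
  if (method == "standep") {
    if (is.null(nClusters)) {
      say("selecting cluster count over N = ", nRange[1], "..", nRange[2])
      selection <- stage("select_n", selectClusterCount(
        enzExpr, catalog, nRange = nRange, jaccardCut = jaccardCut,
        nBins = nBins, distance = distance, linkage = linkage,
        protected = protected))
      nClusters <- selection$n
      say("selected N = ", nClusters)
    }
    clustering <- stage("clustering",
                        clusterEnzymes(enzExpr, nClusters = nClusters,
                                       nBins = nBins, distance = distance,
                                       linkage = linkage))
    thresholds <- stage("thresholds", standepThresholds(clustering, enzExpr))
    if (verbose) {
      cs <- clusterStats(clustering)
      diag <- data.frame(cluster = cs$cluster,
                         mu = signif(cs$mu, 4), sigma = signif(cs$sigma, 4),
                         Theta = signif(thetaNorm(thresholds), 4),
                         cutoff = signif(cutoffValues(thresholds), 4))
      say(paste(utils::capture.output(print(diag)), collapse = "\n"))
    }
    jsonlite::write_json(
      list(n_clusters = clustering@nClusters,
           assignment = as.list(clusterAssignment(clustering)),
           cluster_stats = clusterStats(clustering),
           dataset_stats = datasetStats(clustering),
           distance = distance, linkage = linkage,
           selection_trace = if (is.null(selection)) NULL else
             selection$trace),
      file.path(outDir, "clustering.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(theta_raw = thetaRaw(thresholds),
           theta_norm = thetaNorm(thresholds),
           cutoff_log10 = cutoffValues(thresholds),
           dataset_mean_rule = specialMeanFlag(thresholds)),
      file.path(outDir, "thresholds.json"), digits = NA)
  }

  say("deriving core reactions (", method, ")")
  core <- stage("core", switch(method,
    standep = standepCore(enzExpr, clustering, thresholds, catalog,
                          protected = protected),
    global = globalCore(enzExpr, catalog, topPercentile = topPercentile,
                        protected = protected),
    localT1 = localT1Core(enzExpr, catalog,
                          lowerTopPercentile = lowerTopPercentile,
                          variant = localT1Variant, protected = protected),
    localT2 = localT2Core(enzExpr, catalog,
                          upperTopPercentile = upperTopPercentile,
                          lowerTopPercentile = lowerTopPercentile,
                          protected = protected)))
  writeCoreSets(core, outDir)

  mem <- NULL
  if (method == "standep") {
    mem <- stage("mem_inputs",
                 buildMEMInputs(enzExpr, clustering, thresholds, catalog,
                                protected = protected, core = core,
                                band = band))
    writeMEMInputs(mem, outDir)
  }

  evaluation <- NULL
  if (!is.null(hkReactions) && length(hkReactions)) {
    evaluation <- list(
      coverage = housekeepingCoverage(core, hkReactions))
    if (!is.null(clustering))
      evaluation$enrichment <- clusterEnrichment(clustering, hkReactions,
                                                 catalog)
    jsonlite::write_json(
      list(coverage_mean = evaluation$coverage$mean,
           coverage_per_context = as.list(evaluation$coverage$perContext),
           enrichment = evaluation$enrichment),
      file.path(outDir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  }

  config <- list(method = method, nClusters = nClusters, nRange = nRange,
                 nBins = nBins, distance = distance, linkage = linkage,
                 jaccardCut = jaccardCut, topPercentile = topPercentile,
                 lowerTopPercentile = lowerTopPercentile,
                 upperTopPercentile = upperTopPercentile,
                 localT1Variant = localT1Variant, band = band,
                 missingGenePolicy = missingGenePolicy,
                 protected = protected)
  manifest <- list(
    package = "standep",
    version = as.character(utils::packageVersion("standep")),
    config = config,
    config_hash = .configHash(config),
    n_genes = nrow(expr), n_contexts = ncol(expr),
    n_reactions = length(reactionIds(catalog)),
    n_enzymes_retained = nrow(exprValues(enzExpr)),
    dropped_enzymes = length(droppedEnzymes(enzExpr)),
    core_sizes = lengths(coreSets(core)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done; artifacts in ", outDir)

  invisible(list(enzExpr = enzExpr, clustering = clustering,
                 thresholds = thresholds, core = core, mem = mem,
                 evaluation = evaluation, selection = selection,
                 config = config))
}

## Deterministic config fingerprint without extra dependencies.
.configHash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 251)) %% .Machine$integer.max)
}
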