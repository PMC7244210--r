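#' Accessors for standep S4 classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class
#' @param ... unused
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(x, ...) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("reactionEnzymes", function(x, ...) standardGeneric("reactionEnzymes"))

#' @rdname accessors
#' @export
setGeneric("enzymeIds", function(x, ...) standardGeneric("enzymeIds"))

#' @rdname accessors
#' @export
setGeneric("enzymeGenes", function(x, ...) standardGeneric("enzymeGenes"))

#' @rdname accessors
#' @export
setGeneric("geneFreeReactions", function(x, ...) standardGeneric("geneFreeReactions"))

#' @rdname accessors
#' @export
setGeneric("catalogGenes", function(x, ...) standardGeneric("catalogGenes"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("contextIds", function(x, ...) standardGeneric("contextIds"))

#' @rdname accessors
#' @export
setGeneric("droppedEnzymes", function(x, ...) standardGeneric("droppedEnzymes"))

#' @rdname accessors
#' @export
setGeneric("droppedGenes", function(x, ...) standardGeneric("droppedGenes"))

#' @rdname accessors
#' @export
setGeneric("profileCounts", function(x, ...) standardGeneric("profileCounts"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(x, ...) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x, ...) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("clusterAssignment", function(x, ...) standardGeneric("clusterAssignment"))

#' @rdname accessors
#' @export
setGeneric("clusterStats", function(x, ...) standardGeneric("clusterStats"))

#' @rdname accessors
#' @export
setGeneric("datasetStats", function(x, ...) standardGeneric("datasetStats"))

#' @rdname accessors
#' @export
setGeneric("thetaRaw", function(x, ...) standardGeneric("thetaRaw"))

#' @rdname accessors
#' @export
setGeneric("thetaNorm", function(x, ...) standardGeneric("thetaNorm"))

#' @rdname accessors
#' @export
setGeneric("cutoffValues", function(x, ...) standardGeneric("cutoffValues"))

#' @rdname accessors
#' @export
setGeneric("specialMeanFlag", function(x, ...) standardGeneric("specialMeanFlag"))

#' @rdname accessors
#' @export
setGeneric("coreSets", function(x, ...) standardGeneric("coreSets"))

#' @rdname accessors
#' @export
setGeneric("coreMethod", function(x, ...) standardGeneric("coreMethod"))

#' @rdname accessors
#' @export
setGeneric("coreProvenance", function(x, ...) standardGeneric("coreProvenance"))

#' @rdname accessors
#' @export
setGeneric("protectedReactions", function(x, ...) standardGeneric("protectedReactions"))


## ---- ReactionCatalog ----

#' @rdname accessors
#' @export
setMethod("reactionIds", "ReactionCatalog", function(x) x@reactions$reaction_id)

#' @rdname accessors
#' @export
setMethod("reactionEnzymes", "ReactionCatalog", function(x) x@rxnEnzymes)

#' @rdname accessors
#' @export
setMethod("enzymeIds", "ReactionCatalog", function(x) names(x@enzymes))

#' @rdname accessors
#' @export
setMethod("enzymeGenes", "ReactionCatalog", function(x) x@enzymes)

#' @rdname accessors
#' @export
setMethod("geneFreeReactions", "ReactionCatalog", function(x) x@geneFree)

#' @rdname accessors
#' @export
setMethod("catalogGenes", "ReactionCatalog", function(x)
  sort(unique(unlist(x@enzymes, use.names = FALSE))))

#' @export
setMethod("show", "ReactionCatalog", function(object) {
  cat("ReactionCatalog with", nrow(object@reactions), "reactions,",
      length(object@enzymes), "enzymes,",
      length(catalogGenes(object)), "genes\n")
  cat("  gene-free reactions:", length(object@geneFree), "\n")
  nand <- sum(lengths(object@enzymes) > 1L)
  cat("  multi-gene enzymes (AND complexes):", nand, "\n")
})

## ---- EnzymeExpression ----

#' @rdname accessors
#' @export
setMethod("exprValues", "EnzymeExpression", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("enzymeIds", "EnzymeExpression", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("contextIds", "EnzymeExpression", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("droppedEnzymes", "EnzymeExpression", function(x) x@droppedEnzymes)

#' @rdname accessors
#' @export
setMethod("droppedGenes", "EnzymeExpression", function(x) x@droppedGenes)

#' @export
setMethod("dim", "EnzymeExpression", function(x) dim(x@values))

#' @export
setMethod("show", "EnzymeExpression", function(object) {
  cat("EnzymeExpression:", nrow(object@values), "enzymes x",
      ncol(object@values), "contexts\n")
  if (length(object@droppedEnzymes))
    cat("  dropped enzymes (missing genes):", length(object@droppedEnzymes), "\n")
})

## ---- BinnedProfiles ----

#' @rdname accessors
#' @export
setMethod("profileCounts", "BinnedProfiles", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("binEdges", "BinnedProfiles", function(x) x@binEdges)

#' @rdname accessors
#' @export
setMethod("enzymeIds", "BinnedProfiles", function(x) rownames(x@counts))

#' @export
setMethod("show", "BinnedProfiles", function(object) {
  cat("BinnedProfiles:", nrow(object@counts), "enzymes x",
      ncol(object@counts), "bins on log10 range [",
      round(object@binEdges[1], 3), ",",
      round(object@binEdges[length(object@binEdges)], 3), "]\n")
})

## ---- ClusteringResult ----

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusteringResult", function(x) x@nClusters)

#' @rdname accessors
#' @export
setMethod("clusterAssignment", "ClusteringResult", function(x) x@assignment)

#' @rdname accessors
#' @export
setMethod("clusterStats", "ClusteringResult", function(x) x@clusterStats)

#' @rdname accessors
#' @export
setMethod("datasetStats", "ClusteringResult", function(x)
  list(M = x@datasetMean, Delta = x@datasetSD))

#' @export
setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult:", length(object@assignment), "enzymes in",
      object@nClusters, "clusters (", object@distance, "distance,",
      object@linkage, "linkage)\n")
  cat("  dataset log10 mean M =", signif(object@datasetMean, 4),
      ", SD Delta =", signif(object@datasetSD, 4), "\n")
})

## ---- ThresholdSet ----

#' @rdname accessors
#' @export
setMethod("thetaRaw", "ThresholdSet", function(x) x@thetaRaw)

#' @rdname accessors
#' @export
setMethod("thetaNorm", "ThresholdSet", function(x) x@thetaNorm)

#' @rdname accessors
#' @export
setMethod("cutoffValues", "ThresholdSet", function(x) x@cutoffs)

#' @rdname accessors
#' @export
setMethod("specialMeanFlag", "ThresholdSet", function(x) x@specialMean)

#' @export
setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet (", object@method, "):", length(object@cutoffs),
      "clusters\n")
  df <- data.frame(theta = signif(object@thetaRaw, 4),
                   Theta = signif(object@thetaNorm, 4),
                   cutoff_log10 = signif(object@cutoffs, 4),
                   dataset_mean = object@specialMean)
  print(utils::head(df, 10))
  if (nrow(df) > 10) cat("  ...\n")
})

## ---- CoreReactionSets ----

#' @rdname accessors
#' @export
setMethod("coreSets", "CoreReactionSets", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("coreMethod", "CoreReactionSets", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("coreProvenance", "CoreReactionSets", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("protectedReactions", "CoreReactionSets", function(x) x@protected)

#' @rdname accessors
#' @export
setMethod("contextIds", "CoreReactionSets", function(x) names(x@sets))

#' @export
setMethod("show", "CoreReactionSets", function(object) {
  sz <- lengths(object@sets)
  cat("CoreReactionSets (", object@method, "):", length(object@sets),
      "contexts, core size", min(sz), "-", max(sz),
      "(median", stats::median(sz), ")\n")
})

## ---- MEMInputBundle ----

#' @rdname accessors
#' @export
setMethod("contextIds", "MEMInputBundle", function(x) names(x@fastcoreCore))

#' @export
setMethod("show", "MEMInputBundle", function(object) {
  cat("MEMInputBundle for", length(object@fastcoreCore), "contexts:",
      nrow(object@ubiquity), "reactions\n")
  cat("  components: fastCORE core, iMAT core/non-core, MBA high/medium,",
      "mCADRE ubiquity, INIT weights, GIMME vector (threshold =",
      object@gimmeThreshold, ")\n")
})
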