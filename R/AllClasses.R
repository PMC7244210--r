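#' @import methods
NULL

#' ReactionCatalog: reactions, enzymes and their gene sets
#'
#' A \code{ReactionCatalog} holds the reaction side of a genome-scale
#' metabolic model after GPR (gene-protein-reaction) rules have been
#' decomposed into disjunctive normal form: each OR-separated clause of a
#' GPR becomes one \emph{enzyme} (an AND-set of genes, typically a protein
#' complex), and a reaction maps to one enzyme per isoenzyme. Enzyme complex
#' stoichiometry is not modelled. Enzyme identifiers are canonical: the
#' sorted gene identifiers of the clause joined by \code{"&"}, so two
#' reactions sharing an identical gene set reference the same enzyme.
#'
#' @slot reactions data.frame with columns \code{reaction_id} and
#'   \code{subsystem} (empty string when unknown), one row per reaction.
#' @slot rxnEnzymes named list, \code{reaction_id} -> character vector of
#'   enzyme identifiers (empty for gene-free reactions).
#' @slot enzymes named list, enzyme identifier -> non-empty character vector
#'   of gene identifiers.
#' @slot geneFree character vector of reaction identifiers carrying no gene
#'   association.
#'
#' @seealso [buildReactionCatalog()], [readMetabolicModel()]
#' @exportClass ReactionCatalog
setClass("ReactionCatalog",
  slots = c(
    reactions  = "data.frame",
    rxnEnzymes = "list",
    enzymes    = "list",
    geneFree   = "character"
  )
)

setValidity("ReactionCatalog", function(object) {
  msgs <- character()
  rx <- object@reactions
  if (!all(c("reaction_id", "subsystem") %in% names(rx)))
    msgs <- c(msgs, "reactions must have columns reaction_id, subsystem")
  else {
    if (anyDuplicated(rx$reaction_id))
      msgs <- c(msgs, "duplicated reaction identifiers")
    if (!identical(sort(names(object@rxnEnzymes)), sort(rx$reaction_id)))
      msgs <- c(msgs, "rxnEnzymes names must match reaction identifiers")
  }
  eids <- unique(unlist(object@rxnEnzymes, use.names = FALSE))
  if (!all(eids %in% names(object@enzymes)))
    msgs <- c(msgs, "reaction references an enzyme missing from the enzyme map")
  if (any(lengths(object@enzymes) == 0L))
    msgs <- c(msgs, "every enzyme must have a non-empty gene set")
  canonical <- vapply(object@enzymes, function(g)
    paste(sort(unique(g)), collapse = "&"), character(1))
  if (length(canonical) && !identical(unname(canonical), names(object@enzymes)) &&
      !all(names(object@enzymes) == canonical))
    msgs <- c(msgs, "enzyme identifiers must be canonical (sorted genes joined by '&')")
  gf <- names(object@rxnEnzymes)[lengths(object@rxnEnzymes) == 0L]
  if (!setequal(gf, object@geneFree))
    msgs <- c(msgs, "geneFree must contain exactly the reactions with no enzymes")
  if (length(msgs)) msgs else TRUE
})

#' EnzymeExpression: enzymes-by-contexts abundance matrix
#'
#' Enzyme expression is the combined expression of the enzyme-coding genes of
#' one GPR clause: the minimum over the clause's genes (an AND relationship;
#' the least expressed subunit governs the amount of functional enzyme).
#' Values are nonnegative abundances on the linear scale (e.g. FPKM/TPM);
#' all downstream statistics are computed on log10 of the positive entries.
#'
#' @slot values numeric matrix, enzymes (rows) by contexts (columns).
#' @slot droppedEnzymes enzymes excluded because one or more of their genes
#'   were absent from the expression data (under the \code{"drop"} policy).
#' @slot droppedGenes catalog genes absent from the expression data.
#'
#' @seealso [computeEnzymeExpression()]
#' @exportClass EnzymeExpression
setClass("EnzymeExpression",
  slots = c(
    values         = "matrix",
    droppedEnzymes = "character",
    droppedGenes   = "character"
  )
)

setValidity("EnzymeExpression", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must carry enzyme rownames and context colnames")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicated enzyme ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicated context ids")
  }
  if (is.numeric(v) && any(v < 0)) msgs <- c(msgs, "negative expression values")
  if (length(msgs)) msgs else TRUE
})

#' BinnedProfiles: per-enzyme expression distribution profiles
#'
#' For each enzyme, the number of contexts whose log10 expression falls into
#' each of a set of uniform bins spanning the positive data range. Zeros are
#' excluded, so row sums equal the number of contexts in which the enzyme is
#' expressed at all. These profiles are what gets clustered.
#'
#' @slot counts integer matrix, enzymes by bins.
#' @slot binEdges numeric vector of length \code{ncol(counts) + 1}, strictly
#'   increasing bin edges on the log10 scale.
#'
#' @seealso [binProfiles()]
#' @exportClass BinnedProfiles
setClass("BinnedProfiles",
  slots = c(counts = "matrix", binEdges = "numeric")
)

setValidity("BinnedProfiles", function(object) {
  msgs <- character()
  if (length(object@binEdges) != ncol(object@counts) + 1L)
    msgs <- c(msgs, "binEdges must have length ncol(counts) + 1")
  if (any(diff(object@binEdges) <= 0))
    msgs <- c(msgs, "binEdges must be strictly increasing")
  if (any(object@counts < 0)) msgs <- c(msgs, "negative bin counts")
  if (length(msgs)) msgs else TRUE
})

#' ClusteringResult: enzyme cluster assignment and summary statistics
#'
#' Result of agglomerative clustering of binned expression profiles, cut at
#' \code{nClusters} clusters, together with the per-cluster and whole-dataset
#' log10 statistics that the cluster-specific threshold equations consume:
#' cluster mean \eqn{\mu_c} and standard deviation \eqn{\sigma_c}, dataset
#' mean \eqn{M} and standard deviation \eqn{\Delta}, all computed over the
#' pooled positive log10 values of the member enzymes across contexts.
#'
#' @slot nClusters number of clusters N.
#' @slot assignment named integer vector, enzyme id -> cluster index in 1..N.
#' @slot clusterStats data.frame with one row per cluster: \code{cluster},
#'   \code{n_enzymes}, \code{n_values} (positive entries pooled), \code{mu},
#'   \code{sigma}.
#' @slot datasetMean,datasetSD mean and standard deviation of all positive
#'   log10 values (M and Delta).
#' @slot distance,linkage the distance metric and agglomeration method used.
#'
#' @seealso [clusterProfiles()], [rawClusterThresholds()]
#' @exportClass ClusteringResult
setClass("ClusteringResult",
  slots = c(
    nClusters    = "integer",
    assignment   = "integer",
    clusterStats = "data.frame",
    datasetMean  = "numeric",
    datasetSD    = "numeric",
    distance     = "character",
    linkage      = "character"
  )
)

setValidity("ClusteringResult", function(object) {
  msgs <- character()
  if (object@nClusters < 1L) msgs <- c(msgs, "nClusters must be >= 1")
  a <- object@assignment
  if (is.null(names(a))) msgs <- c(msgs, "assignment must be named by enzyme id")
  if (length(a) && (min(a) < 1L || max(a) > object@nClusters))
    msgs <- c(msgs, "assignment indices outside 1..nClusters")
  cs <- object@clusterStats
  need <- c("cluster", "n_enzymes", "n_values", "mu", "sigma")
  if (!all(need %in% names(cs)))
    msgs <- c(msgs, "clusterStats missing required columns")
  else if (any(cs$sigma < 0)) msgs <- c(msgs, "sigma must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' ThresholdSet: resolved cluster-specific expression cutoffs
#'
#' Holds, per cluster, the raw threshold \eqn{\theta_c}, its normalisation
#' \eqn{\Theta_c \in [0, 100]}, and the resolved cutoff on the log10
#' expression scale. \eqn{\Theta_c} is the top percentile of the cluster's
#' pooled values above which a member enzyme is qualified active; a cluster
#' at \eqn{\Theta_c = 100} instead takes the dataset mean M as its cutoff
#' (flagged in \code{specialMean}).
#'
#' @slot method character tag, e.g. \code{"standep"}.
#' @slot thetaRaw,thetaNorm numeric per-cluster raw and normalised thresholds.
#' @slot cutoffs numeric per-cluster cutoff values (log10 units).
#' @slot specialMean logical per cluster, TRUE when the dataset-mean rule
#'   applied.
#' @slot params list of the parameters used to derive the thresholds.
#'
#' @seealso [resolveCutoffs()], [standepThresholds()]
#' @exportClass ThresholdSet
setClass("ThresholdSet",
  slots = c(
    method      = "character",
    thetaRaw    = "numeric",
    thetaNorm   = "numeric",
    cutoffs     = "numeric",
    specialMean = "logical",
    params      = "list"
  )
)

setValidity("ThresholdSet", function(object) {
  msgs <- character()
  n <- length(object@cutoffs)
  if (length(object@thetaNorm) != n || length(object@specialMean) != n)
    msgs <- c(msgs, "thetaNorm, cutoffs and specialMean must have equal length")
  if (length(object@thetaNorm) &&
      (min(object@thetaNorm) < -1e-9 || max(object@thetaNorm) > 100 + 1e-9))
    msgs <- c(msgs, "thetaNorm outside [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' CoreReactionSets: per-context active (core) reactions
#'
#' For every context, the set of reactions supported by at least one active
#' enzyme under a thresholding method, plus any explicitly protected
#' reactions (e.g. biomass) that are appended to every context. Provenance
#' records which enzyme activated which reaction in which context.
#'
#' @slot method thresholding method tag
#'   (\code{"standep"}, \code{"global"}, \code{"localT1"}, \code{"localT2"}).
#' @slot sets named list, context id -> character vector of reaction ids.
#' @slot provenance data.frame with columns \code{context},
#'   \code{reaction_id}, \code{enzyme_id} (activating enzyme).
#' @slot protected character vector of always-included reaction ids.
#'
#' @seealso [standepCore()], [globalCore()], [localT1Core()], [localT2Core()]
#' @exportClass CoreReactionSets
setClass("CoreReactionSets",
  slots = c(
    method     = "character",
    sets       = "list",
    provenance = "data.frame",
    protected  = "character"
  )
)

setValidity("CoreReactionSets", function(object) {
  msgs <- character()
  if (is.null(names(object@sets))) msgs <- c(msgs, "sets must be named by context")
  if (length(msgs)) msgs else TRUE
})

#' MEMInputBundle: tailored inputs for six model-extraction methods
#'
#' Container for the expression-derived inputs consumed by fastCORE (core
#' reaction lists), iMAT (core / non-core partition), MBA (high / medium
#' expression sets), mCADRE (reaction ubiquity scores), INIT (reaction
#' weights) and GIMME (reaction expression vector plus activity threshold).
#' The extraction algorithms themselves are out of scope; this bundle is what
#' they would be fed.
#'
#' @slot fastcoreCore,imatCore,imatNoncore,mbaHigh,mbaMedium named lists
#'   (context -> character vector of reaction ids).
#' @slot ubiquity numeric matrix, reactions by contexts, in [0, 1] for
#'   gene-associated reactions and -1 for reactions without expression
#'   evidence.
#' @slot initWeights,gimmeWeights numeric matrices, reactions by contexts.
#' @slot gimmeThreshold the GIMME activity threshold (fixed at 1).
#' @slot protected reaction ids forced into core / assigned weight 1.
#'
#' @seealso [buildMEMInputs()]
#' @exportClass MEMInputBundle
setClass("MEMInputBundle",
  slots = c(
    fastcoreCore   = "list",
    imatCore       = "list",
    imatNoncore    = "list",
    mbaHigh        = "list",
    mbaMedium      = "list",
    ubiquity       = "matrix",
    initWeights    = "matrix",
    gimmeWeights   = "matrix",
    gimmeThreshold = "numeric",
    protected      = "character"
  )
)
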