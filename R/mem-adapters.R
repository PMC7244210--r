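## Tailoring cluster-thresholded expression into the inputs of the six
## model-extraction methods (fastCORE, iMAT, MBA, mCADRE, INIT, GIMME).

#' Threshold distances of enzyme expression from cluster cutoffs
#'
#' The signed distance, on the log10 scale, of each enzyme's expression in
#' each context from the resolved cutoff of the enzyme's cluster:
#' \eqn{D = \log_{10} x - \mathrm{cutoff}}. Positive distances mark enzymes
#' the cluster-specific thresholding calls active. Zero-expression entries
#' have no log value; they are placed at a documented floor, by default one
#' decade below the smallest positive value of the dataset, before
#' subtracting the cutoff.
#'
#' @param enzExpr an [EnzymeExpression-class] or numeric matrix.
#' @param clustering the [ClusteringResult-class] covering the enzymes.
#' @param thresholds a [ThresholdSet-class].
#' @param zeroFloor log10 value standing in for zero expression; default
#'   \code{log10(min positive value) - zeroFloorOffset}.
#' @param zeroFloorOffset decades below the minimum positive value used for
#'   the default floor (default 1).
#' @return numeric enzymes-by-contexts matrix of distances (log10 units).
#' @export
thresholdDistances <- function(enzExpr, clustering, thresholds,
                               zeroFloor = NULL, zeroFloorOffset = 1) {
  m <- .enzymeMatrix(enzExpr)
  cl <- .alignedClusters(m, clustering)
  cutoffs <- cutoffValues(thresholds)[cl]
  if (is.null(zeroFloor)) {
    pos <- m[m > 0]
    if (!length(pos)) stop("matrix contains no positive values")
    zeroFloor <- log10(min(pos)) - zeroFloorOffset
  }
  lv <- .log10OrNegInf(m)
  lv[!is.finite(lv)] <- zeroFloor
  D <- lv - cutoffs
  dimnames(D) <- dimnames(m)
  D
}

## Reaction-level score from an enzyme-level matrix: f over member enzymes.
.reactionScore <- function(E, catalog, combine, noDataValue, protected,
                           protectedValue) {
  rids <- reactionIds(catalog)
  out <- matrix(noDataValue, nrow = length(rids), ncol = ncol(E),
                dimnames = list(rids, colnames(E)))
  for (rid in rids) {
    eids <- intersect(catalog@rxnEnzymes[[rid]], rownames(E))
    if (!length(eids)) next
    out[rid, ] <- combine(E[eids, , drop = FALSE])
  }
  protected <- intersect(protected, rids)
  if (length(protected)) out[protected, ] <- protectedValue
  out
}

#' Reaction ubiquity scores for mCADRE
#'
#' Converts threshold distances into per-reaction evidence scores in [0, 1]:
#' \deqn{D > 0 \Rightarrow U = 1; \qquad
#'       D < 0 \Rightarrow U = 1 - D / \min(D)}
#' with \eqn{\min(D)} the most negative distance anywhere in the matrix, so
#' the farthest-below-threshold enzyme scores 0 and the boundary
#' \eqn{D = 0} scores 1. Reactions take the maximum score over their
#' isoenzymes. Reactions with no gene association -- and reactions whose
#' enzymes were all dropped during gene matching, which carry no expression
#' evidence either -- are marked with the sentinel -1. Protected reactions
#' score 1 everywhere.
#'
#' @param D distance matrix from [thresholdDistances()].
#' @param catalog a [ReactionCatalog-class].
#' @param protected reaction ids assigned a score of 1 (e.g. biomass).
#' @return numeric reactions-by-contexts matrix.
#' @export
ubiquityScores <- function(D, catalog, protected = character()) {
  if (any(!is.finite(D))) stop("distance matrix must be finite")
  neg <- D[D < 0]
  U <- matrix(1, nrow = nrow(D), ncol = ncol(D), dimnames = dimnames(D))
  if (length(neg)) {
    mn <- min(neg)
    idx <- D < 0
    U[idx] <- 1 - D[idx] / mn
  } else {
    warning("no negative threshold distances; all gene-associated ",
            "ubiquity scores are 1")
  }
  .reactionScore(U, catalog, combine = function(x) apply(x, 2, max),
                 noDataValue = -1, protected = protected,
                 protectedValue = 1)
}

#' Reaction weights for INIT
#'
#' Enzyme weights are the threshold distances scaled by the maximum absolute
#' distance anywhere in the data, so they lie in [-1, 1]; a reaction's weight
#' is the \emph{sum} of its isoenzymes' weights (and may therefore exceed 1
#' in magnitude; no clipping is applied). Gene-free reactions, and reactions
#' with no retained enzymes, weigh 0. Protected reactions weigh 1.
#'
#' @inheritParams ubiquityScores
#' @return numeric reactions-by-contexts weight matrix.
#' @export
initWeights <- function(D, catalog, protected = character()) {
  if (any(!is.finite(D))) stop("distance matrix must be finite")
  mx <- max(abs(D))
  if (mx == 0) {
    warning("all threshold distances are zero; all weights are 0")
    W <- D
  } else {
    W <- D / mx
  }
  .reactionScore(W, catalog, combine = colSums,
                 noDataValue = 0, protected = protected, protectedValue = 1)
}

#' Reaction expression vector and activity threshold for GIMME
#'
#' The GIMME expression vector is constructed exactly as the INIT weights
#' ([initWeights()]); the activity threshold accompanying it is fixed at 1.
#'
#' @inheritParams ubiquityScores
#' @return list with elements \code{weights} (reactions-by-contexts matrix)
#'   and \code{threshold} (1).
#' @export
gimmeInputs <- function(D, catalog, protected = character()) {
  list(weights = initWeights(D, catalog, protected = protected),
       threshold = 1)
}

#' High and medium expression reaction sets for MBA
#'
#' Per enzyme, expression is compared against a multiplicative band around
#' the resolved cutoff of its cluster: above \code{(1 + band)} times the
#' cutoff is high, within \code{(1 - band)} to \code{(1 + band)} times the
#' cutoff is medium (default band 0.10, i.e. 90--110 percent). By default
#' the band is applied on the linear expression scale (the cutoff is
#' back-transformed from log10); \code{scale = "log"} bands the log10 cutoff
#' instead. A reaction found in both sets is interpreted as having at least
#' one highly expressed isoenzyme and kept in the high set only. Protected
#' reactions go to the high set.
#'
#' @inheritParams standepCore
#' @param band half-width of the relative band (must be < 1; default 0.10).
#' @param scale \code{"linear"} (default) or \code{"log"}.
#' @return list with named lists \code{high} and \code{medium}
#'   (context -> reaction ids), disjoint per context.
#' @export
mbaSets <- function(enzExpr, clustering, thresholds, catalog, band = 0.10,
                    scale = c("linear", "log"), protected = character()) {
  scale <- match.arg(scale)
  if (band >= 1) stop("band must be below 1")
  m <- .enzymeMatrix(enzExpr)
  cl <- .alignedClusters(m, clustering)
  cutoff <- cutoffValues(thresholds)[cl]
  if (scale == "linear") {
    cutLin <- 10^cutoff
    x <- m
    lo <- pmin((1 - band) * cutLin, (1 + band) * cutLin)
    hi <- pmax((1 - band) * cutLin, (1 + band) * cutLin)
  } else {
    x <- .log10OrNegInf(m)
    lo <- pmin((1 - band) * cutoff, (1 + band) * cutoff)
    hi <- pmax((1 - band) * cutoff, (1 + band) * cutoff)
  }
  highE <- x > hi
  medE <- x >= lo & x <= hi
  e2r <- .enzymeToReactions(catalog)
  protected <- intersect(unique(as.character(protected)),
                         reactionIds(catalog))
  ctxs <- colnames(m)
  high <- medium <- stats::setNames(vector("list", length(ctxs)), ctxs)
  for (j in seq_along(ctxs)) {
    eh <- rownames(m)[highE[, j]]
    em <- rownames(m)[medE[, j]]
    rh <- unique(unlist(e2r[intersect(eh, names(e2r))], use.names = FALSE))
    rm_ <- unique(unlist(e2r[intersect(em, names(e2r))], use.names = FALSE))
    rh <- union(if (is.null(rh)) character(0) else rh, protected)
    rm_ <- setdiff(if (is.null(rm_)) character(0) else rm_, rh)
    high[[j]] <- rh
    medium[[j]] <- rm_
  }
  list(high = high, medium = medium)
}

#' Core / non-core partition for iMAT
#'
#' Non-core reactions are all catalog reactions that are neither core nor
#' gene-free (reactions without a gene association belong to neither set).
#'
#' @param core a [CoreReactionSets-class] (already including protected
#'   reactions).
#' @param catalog a [ReactionCatalog-class].
#' @return list with named lists \code{core} and \code{noncore}
#'   (context -> reaction ids).
#' @export
imatSets <- function(core, catalog) {
  allR <- reactionIds(catalog)
  gf <- geneFreeReactions(catalog)
  sets <- coreSets(core)
  noncore <- lapply(sets, function(s) setdiff(allR, union(s, gf)))
  list(core = sets, noncore = noncore)
}

#' Assemble the inputs of all six model-extraction methods
#'
#' Computes threshold distances, ubiquity scores, INIT/GIMME weight matrices
#' and the MBA, iMAT and fastCORE reaction sets from one clustering +
#' threshold set, returning them in a single [MEMInputBundle-class].
#'
#' @inheritParams standepCore
#' @param core optional precomputed [CoreReactionSets-class]; computed via
#'   [standepCore()] when omitted.
#' @param band MBA band half-width, see [mbaSets()].
#' @param zeroFloorOffset see [thresholdDistances()].
#' @return a [MEMInputBundle-class].
#' @export
buildMEMInputs <- function(enzExpr, clustering, thresholds, catalog,
                           protected = character(), core = NULL,
                           band = 0.10, zeroFloorOffset = 1) {
  if (is.null(core))
    core <- standepCore(enzExpr, clustering, thresholds, catalog,
                        protected = protected)
  D <- thresholdDistances(enzExpr, clustering, thresholds,
                          zeroFloorOffset = zeroFloorOffset)
  U <- ubiquityScores(D, catalog, protected = protected)
  W <- initWeights(D, catalog, protected = protected)
  gim <- gimmeInputs(D, catalog, protected = protected)
  mba <- mbaSets(enzExpr, clustering, thresholds, catalog, band = band,
                 protected = protected)
  im <- imatSets(core, catalog)
  new("MEMInputBundle",
      fastcoreCore = coreSets(core),
      imatCore = im$core,
      imatNoncore = im$noncore,
      mbaHigh = mba$high,
      mbaMedium = mba$medium,
      ubiquity = U,
      initWeights = W,
      gimmeWeights = gim$weights,
      gimmeThreshold = gim$threshold,
      protected = unique(as.character(protected)))
}

#' Write a MEMInputBundle to disk
#'
#' One JSON with every component plus per-method delimited files: reaction-id
#' lists per context for fastCORE/iMAT/MBA and reactions-by-contexts TSV
#' matrices for the ubiquity, INIT and GIMME components.
#'
#' @param bundle a [MEMInputBundle-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeMEMInputs <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMat <- function(m, file) {
    df <- data.frame(reaction_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  writeMat(bundle@ubiquity, "mcadre_ubiquity.tsv")
  writeMat(bundle@initWeights, "init_weights.tsv")
  writeMat(bundle@gimmeWeights, "gimme_weights.tsv")
  obj <- list(
    fastcore_core = lapply(bundle@fastcoreCore, as.list),
    imat_core = lapply(bundle@imatCore, as.list),
    imat_noncore = lapply(bundle@imatNoncore, as.list),
    mba_high = lapply(bundle@mbaHigh, as.list),
    mba_medium = lapply(bundle@mbaMedium, as.list),
    gimme_threshold = bundle@gimmeThreshold,
    protected = as.list(bundle@protected))
  jsonlite::write_json(obj, file.path(dir, "mem_inputs.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
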