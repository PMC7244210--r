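## Cluster-specific thresholds and the three baseline thresholding schemes.

#' Raw cluster-specific thresholds from cluster statistics
#'
#' The raw threshold of cluster c combines a standard-deviation term and a
#' mean term, each measured against the whole dataset:
#' \deqn{\theta_c = f(\sigma_c) + g(\mu_c)}
#' \deqn{f(\sigma_c) = (\sigma_c - \Delta) / \max_c(\sigma_c - \Delta)}
#' \deqn{g(\mu_c) = -(\mu_c - M)}
#' where \eqn{\mu_c, \sigma_c} are the cluster's log10 mean and standard
#' deviation and \eqn{M, \Delta} the dataset's. Low-mean clusters are thus
#' rewarded (their members need lower absolute expression to qualify), and
#' the standard-deviation term measures how tight a cluster is relative to
#' the dataset.
#'
#' If every cluster's standard deviation equals \eqn{\Delta} the denominator
#' vanishes; f is then defined as 0 for all clusters with a warning. When all
#' clusters are tighter than the dataset the denominator is negative, which
#' inverts the sign of f exactly as the formula dictates (tight clusters
#' rewarded); a warning notes the regime.
#'
#' @param clustering a [ClusteringResult-class].
#' @return named numeric vector of raw thresholds, one per cluster.
#' @seealso [normalizeThresholds()], [resolveCutoffs()]
#' @export
rawClusterThresholds <- function(clustering) {
  cs <- clusterStats(clustering)
  if (!nrow(cs)) stop("clustering has no clusters")
  Delta <- clustering@datasetSD
  M <- clustering@datasetMean
  d <- cs$sigma - Delta
  dm <- max(d)
  if (abs(dm) < .Machine$double.eps * 100) {
    warning("max(sigma_c - Delta) is zero; standard-deviation term set to 0")
    f <- rep(0, nrow(cs))
  } else {
    if (dm < 0)
      warning("every cluster is tighter than the dataset ",
              "(max(sigma_c - Delta) < 0); sign preserved as written")
    f <- d / dm
  }
  g <- -(cs$mu - M)
  stats::setNames(f + g, as.character(cs$cluster))
}

#' Normalise raw thresholds onto [0, 100]
#'
#' Affine map \eqn{\Theta_c = (\theta_c - \min\theta) \cdot 100 /
#' \max(\theta_c - \min\theta)}: the smallest raw threshold maps to 0, the
#' largest to 100. If all raw thresholds are identical the map is undefined;
#' every cluster is then assigned 100 (the dataset-mean special case) with a
#' warning.
#'
#' @param theta numeric vector of raw thresholds (>= 2 clusters).
#' @return numeric vector of normalised thresholds in [0, 100].
#' @export
normalizeThresholds <- function(theta) {
  if (length(theta) < 2L)
    stop("normalisation needs at least two clusters")
  rng <- max(theta) - min(theta)
  if (rng < .Machine$double.eps * 100) {
    warning("all raw thresholds identical; every cluster takes the ",
            "dataset-mean cutoff (Theta = 100)")
    return(stats::setNames(rep(100, length(theta)), names(theta)))
  }
  (theta - min(theta)) * 100 / rng
}

#' Resolve normalised thresholds to expression-value cutoffs
#'
#' \eqn{\Theta_c} is the top percentile of the cluster's pooled data above
#' which a member enzyme qualifies as active: the cutoff is the quantile at
#' probability \eqn{(100 - \Theta_c)/100} of the cluster's pooled positive
#' log10 member values (linear interpolation). \eqn{\Theta_c = 0} therefore
#' resolves to the cluster maximum (nothing strictly exceeds it), and
#' \eqn{\Theta_c = 100} is special-cased to the dataset mean M.
#'
#' @param thetaNorm numeric vector of normalised thresholds in [0, 100],
#'   one per cluster (in cluster order).
#' @param clustering the [ClusteringResult-class] the thresholds belong to.
#' @param enzExpr the enzyme expression used for clustering.
#' @param thetaRaw optional raw thresholds, stored for provenance.
#' @return a [ThresholdSet-class].
#' @export
resolveCutoffs <- function(thetaNorm, clustering, enzExpr,
                           thetaRaw = numeric()) {
  m <- .enzymeMatrix(enzExpr)
  if (length(thetaNorm) != clustering@nClusters)
    stop("need one normalised threshold per cluster")
  if (any(thetaNorm < -1e-9 | thetaNorm > 100 + 1e-9))
    stop("normalised thresholds must lie in [0, 100]")
  a <- clustering@assignment
  lv <- .log10OrNegInf(m)
  cutoffs <- numeric(clustering@nClusters)
  special <- logical(clustering@nClusters)
  for (k in seq_len(clustering@nClusters)) {
    rows <- names(a)[a == k]
    if (!length(rows)) stop("cluster ", k, " is empty")
    v <- lv[rows, , drop = FALSE]
    v <- v[is.finite(v)]
    if (!length(v)) stop("cluster ", k, " has no positive values")
    if (thetaNorm[k] >= 100 - 1e-9) {
      cutoffs[k] <- clustering@datasetMean
      special[k] <- TRUE
    } else {
      cutoffs[k] <- topPercentileCutoff(v, thetaNorm[k])
    }
  }
  new("ThresholdSet", method = "standep",
      thetaRaw = as.numeric(thetaRaw),
      thetaNorm = as.numeric(thetaNorm),
      cutoffs = cutoffs, specialMean = special,
      params = list())
}

#' Cluster-specific thresholds in one step
#'
#' Runs [rawClusterThresholds()], [normalizeThresholds()] and
#' [resolveCutoffs()] in sequence.
#'
#' @inheritParams resolveCutoffs
#' @return a [ThresholdSet-class].
#' @export
standepThresholds <- function(clustering, enzExpr) {
  theta <- rawClusterThresholds(clustering)
  Theta <- normalizeThresholds(theta)
  resolveCutoffs(Theta, clustering, enzExpr, thetaRaw = theta)
}

## Shared: from an enzymes-by-contexts logical activity matrix to per-context
## core reaction sets with provenance.
.coreFromActive <- function(active, catalog, protected, method,
                            keepProvenance = TRUE) {
  protected <- unique(as.character(protected))
  unknown <- setdiff(protected, reactionIds(catalog))
  if (length(unknown))
    warning("protected reactions not in the catalog: ",
            paste(unknown, collapse = ", "))
  e2r <- .enzymeToReactions(catalog)
  ctxs <- colnames(active)
  sets <- vector("list", length(ctxs))
  names(sets) <- ctxs
  prov <- if (keepProvenance) vector("list", length(ctxs)) else NULL
  for (j in seq_along(ctxs)) {
    eact <- rownames(active)[active[, j]]
    eact <- eact[eact %in% names(e2r)]
    rxns <- unique(unlist(e2r[eact], use.names = FALSE))
    sets[[j]] <- union(if (is.null(rxns)) character(0) else rxns, protected)
    if (keepProvenance && length(eact)) {
      n <- lengths(e2r[eact])
      prov[[j]] <- data.frame(context = ctxs[j],
                              reaction_id = unlist(e2r[eact],
                                                   use.names = FALSE),
                              enzyme_id = rep(eact, n),
                              stringsAsFactors = FALSE)
    }
  }
  provDf <- if (keepProvenance && length(prov))
    do.call(rbind, prov[!vapply(prov, is.null, logical(1))])
  else NULL
  if (is.null(provDf))
    provDf <- data.frame(context = character(), reaction_id = character(),
                         enzyme_id = character(), stringsAsFactors = FALSE)
  new("CoreReactionSets", method = method, sets = sets,
      provenance = provDf, protected = protected)
}

#' Core reactions under cluster-specific thresholds
#'
#' An enzyme is active in a context when its log10 expression strictly
#' exceeds the cutoff of its cluster (zeros are never active); a reaction is
#' core when at least one of its enzymes is active (isoenzyme OR semantics).
#' Protected reactions (e.g. biomass) are appended to every context's core.
#'
#' @param enzExpr an [EnzymeExpression-class] or numeric matrix.
#' @param clustering the [ClusteringResult-class] covering the enzymes.
#' @param thresholds a [ThresholdSet-class] from [standepThresholds()].
#' @param catalog a [ReactionCatalog-class].
#' @param protected reaction ids always added to every context's core.
#' @param keepProvenance record activating enzymes per (reaction, context)
#'   (default TRUE; disable for speed in scans).
#' @return a [CoreReactionSets-class].
#' @export
standepCore <- function(enzExpr, clustering, thresholds, catalog,
                        protected = character(), keepProvenance = TRUE) {
  m <- .enzymeMatrix(enzExpr)
  cl <- .alignedClusters(m, clustering)
  if (length(cutoffValues(thresholds)) < clustering@nClusters)
    stop("thresholds do not cover every cluster")
  lv <- .log10OrNegInf(m)
  active <- lv > cutoffValues(thresholds)[cl]
  dimnames(active) <- dimnames(m)
  .coreFromActive(active, catalog, protected, "standep",
                  keepProvenance = keepProvenance)
}

#' Core reactions under a single global threshold
#'
#' The classical approach: one cutoff for the whole dataset, the top
#' \code{topPercentile} percentile of all positive log10 enzyme expression
#' values. An enzyme is active wherever its value strictly exceeds the
#' cutoff.
#'
#' @inheritParams standepCore
#' @param topPercentile the "top X percent" of the pooled data considered
#'   active (default 25, i.e. the 75th-percentile cutoff).
#' @return a [CoreReactionSets-class].
#' @export
globalCore <- function(enzExpr, catalog, topPercentile = 25,
                       protected = character(), keepProvenance = TRUE) {
  m <- .enzymeMatrix(enzExpr)
  cutoff <- topPercentileCutoff(.pooledLog10(m), topPercentile)
  lv <- .log10OrNegInf(m)
  active <- lv > cutoff
  dimnames(active) <- dimnames(m)
  out <- .coreFromActive(active, catalog, protected, "global",
                         keepProvenance = keepProvenance)
  out
}

## Per-enzyme mean of positive log10 values; -Inf when never expressed.
.enzymeLogMeans <- function(m) {
  lv <- .log10OrNegInf(m)
  apply(lv, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r)) mean(r) else -Inf
  })
}

#' Core reactions under the localT1 scheme
#'
#' Local thresholding with one dataset-level bound, the top
#' \code{lowerTopPercentile} percentile (default 75, i.e. the 25th-percentile
#' value) of the pooled positive log10 data.
#'
#' Two published formulations exist and they disagree; both are provided:
#' \describe{
#'   \item{\code{"methods"} (default)}{enzymes whose cross-context mean falls
#'     below the bound are unconditionally inactive in all contexts; every
#'     other enzyme is active wherever its expression strictly exceeds its
#'     own mean.}
#'   \item{\code{"results"}}{no unconditional inactivation: each enzyme's
#'     cutoff is the larger of its own mean and the dataset bound.}
#' }
#' Enzyme means are taken over the positive log10 values of that enzyme.
#'
#' @inheritParams standepCore
#' @param lowerTopPercentile top percentile defining the dataset lower bound
#'   (default 75).
#' @param variant \code{"methods"} or \code{"results"}; see Details.
#' @return a [CoreReactionSets-class].
#' @export
localT1Core <- function(enzExpr, catalog, lowerTopPercentile = 75,
                        variant = c("methods", "results"),
                        protected = character(), keepProvenance = TRUE) {
  variant <- match.arg(variant)
  m <- .enzymeMatrix(enzExpr)
  lowerCut <- topPercentileCutoff(.pooledLog10(m), lowerTopPercentile)
  mu <- .enzymeLogMeans(m)
  lv <- .log10OrNegInf(m)
  active <- if (variant == "methods") {
    act <- lv > mu            # row-recycled per enzyme
    act[mu < lowerCut, ] <- FALSE
    act
  } else {
    lv > pmax(mu, lowerCut)
  }
  dimnames(active) <- dimnames(m)
  .coreFromActive(active, catalog, protected, "localT1",
                  keepProvenance = keepProvenance)
}

#' Core reactions under the localT2 scheme
#'
#' Local thresholding with two dataset-level bounds: the top
#' \code{upperTopPercentile} percentile (default 25) and the top
#' \code{lowerTopPercentile} percentile (default 75) of the pooled positive
#' log10 data. Enzymes whose cross-context mean lies below the lower bound
#' are inactive in all contexts; enzymes whose mean lies above the upper
#' bound are active in \emph{all} contexts (even where measured zero);
#' enzymes in between are active wherever expression strictly exceeds their
#' own mean.
#'
#' @inheritParams localT1Core
#' @param upperTopPercentile top percentile defining the unconditional-active
#'   bound (default 25).
#' @return a [CoreReactionSets-class].
#' @export
localT2Core <- function(enzExpr, catalog, upperTopPercentile = 25,
                        lowerTopPercentile = 75, protected = character(),
                        keepProvenance = TRUE) {
  m <- .enzymeMatrix(enzExpr)
  pool <- .pooledLog10(m)
  upperCut <- topPercentileCutoff(pool, upperTopPercentile)
  lowerCut <- topPercentileCutoff(pool, lowerTopPercentile)
  if (lowerCut >= upperCut)
    stop("lower bound is not below upper bound after quantile resolution")
  mu <- .enzymeLogMeans(m)
  lv <- .log10OrNegInf(m)
  active <- lv > mu
  active[mu < lowerCut, ] <- FALSE
  active[mu > upperCut, ] <- TRUE
  dimnames(active) <- dimnames(m)
  .coreFromActive(active, catalog, protected, "localT2",
                  keepProvenance = keepProvenance)
}

#' Write core reaction sets to disk
#'
#' Writes one reaction-per-line text file per context plus a single JSON map
#' (context -> reaction ids), and the provenance table as TSV when present.
#'
#' @param core a [CoreReactionSets-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCoreSets <- function(core, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- coreSets(core)
  for (ctx in names(sets)) {
    writeLines(sort(sets[[ctx]]),
               file.path(dir, paste0("core_", coreMethod(core), "_",
                                     gsub("[^A-Za-z0-9_.-]", "_", ctx),
                                     ".txt")))
  }
  jsonlite::write_json(lapply(sets, as.list),
                       file.path(dir, paste0("core_", coreMethod(core),
                                             ".json")))
  prov <- coreProvenance(core)
  if (nrow(prov))
    utils::write.table(prov, file.path(dir, paste0("provenance_",
                                                   coreMethod(core), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
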