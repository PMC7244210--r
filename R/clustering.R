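## Binned expression profiles, hierarchical clustering, cluster-count
## selection by core-list stability.

#' Bin log10 enzyme expression into per-enzyme distribution profiles
#'
#' Lays \code{nBins} uniform bins on the log10 scale across the positive
#' data range (from the log10 minimum positive value to the log10 maximum)
#' and counts, per enzyme, the number of contexts whose value falls in each
#' bin. Zeros are excluded: the profile encodes in how many contexts, and at
#' what level, an enzyme is expressed at all.
#'
#' @param enzExpr an [EnzymeExpression-class] or numeric matrix.
#' @param nBins number of bins (default 60, resolving ~8 decades of
#'   abundance at about 0.13 decades per bin).
#' @return a [BinnedProfiles-class].
#' @export
binProfiles <- function(enzExpr, nBins = 60L) {
  m <- .enzymeMatrix(enzExpr)
  if (nBins < 1L) stop("nBins must be a positive integer")
  pos <- m[m > 0]
  if (!length(pos)) stop("expression matrix is all zero; nothing to bin")
  lo <- log10(min(pos))
  hi <- log10(max(pos))
  if (hi - lo < 1e-9) hi <- lo + 1e-6  # degenerate single-value range
  edges <- seq(lo, hi, length.out = nBins + 1L)
  counts <- t(apply(m, 1, function(row) {
    lv <- log10(row[row > 0])
    if (!length(lv)) return(integer(nBins))
    tabulate(findInterval(lv, edges, rightmost.closed = TRUE), nbins = nBins)
  }))
  if (nBins == 1L) counts <- matrix(as.integer(counts), ncol = 1L,
                                    dimnames = list(rownames(m), NULL))
  storage.mode(counts) <- "integer"
  rownames(counts) <- rownames(m)
  colnames(counts) <- paste0("bin", seq_len(nBins))
  new("BinnedProfiles", counts = counts, binEdges = edges)
}

#' Hierarchically cluster binned expression profiles
#'
#' Agglomerative clustering (default Euclidean distance, complete linkage)
#' of the per-enzyme profiles, cut at \code{nClusters}. Cluster statistics
#' (\eqn{\mu_c}, \eqn{\sigma_c}) and dataset statistics (M, \eqn{\Delta})
#' are computed from the pooled positive log10 values of the member enzymes
#' across contexts, the same transform used for binning.
#'
#' @param profiles a [BinnedProfiles-class] from [binProfiles()].
#' @param enzExpr the enzyme expression the profiles were built from.
#' @param nClusters number of clusters N (1 <= N <= number of enzymes).
#' @param distance distance metric passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return a [ClusteringResult-class].
#' @export
clusterProfiles <- function(profiles, enzExpr, nClusters,
                            distance = "euclidean", linkage = "complete") {
  m <- .enzymeMatrix(enzExpr)
  counts <- profileCounts(profiles)
  if (!identical(rownames(counts), rownames(m)))
    stop("profiles and enzyme expression cover different enzymes")
  nClusters <- as.integer(nClusters)
  if (is.na(nClusters) || nClusters < 1L)
    stop("nClusters must be a positive integer")
  if (nClusters > nrow(counts))
    stop("nClusters exceeds the number of enzymes")

  assignment <- if (nClusters == nrow(counts)) {
    stats::setNames(seq_len(nrow(counts)), rownames(counts))
  } else {
    hc <- stats::hclust(stats::dist(counts, method = distance),
                        method = linkage)
    stats::cutree(hc, k = nClusters)
  }
  .clusteringFromAssignment(m, assignment, nClusters, distance, linkage)
}

.clusteringFromAssignment <- function(m, assignment, nClusters,
                                      distance, linkage) {
  pooled <- .pooledLog10(m)
  lv <- .log10OrNegInf(m)
  stats_df <- do.call(rbind, lapply(seq_len(nClusters), function(k) {
    rows <- names(assignment)[assignment == k]
    v <- lv[rows, , drop = FALSE]
    v <- v[is.finite(v)]
    data.frame(cluster = k,
               n_enzymes = length(rows),
               n_values = length(v),
               mu = if (length(v)) mean(v) else NA_real_,
               sigma = if (length(v) > 1L) stats::sd(v) else 0)
  }))
  new("ClusteringResult",
      nClusters = as.integer(nClusters),
      assignment = stats::setNames(as.integer(assignment), names(assignment)),
      clusterStats = stats_df,
      datasetMean = mean(pooled),
      datasetSD = stats::sd(pooled),
      distance = distance,
      linkage = linkage)
}

#' Bin and cluster enzyme expression in one step
#'
#' Convenience wrapper: [binProfiles()] followed by [clusterProfiles()].
#'
#' @inheritParams clusterProfiles
#' @inheritParams binProfiles
#' @return a [ClusteringResult-class].
#' @export
clusterEnzymes <- function(enzExpr, nClusters, nBins = 60L,
                           distance = "euclidean", linkage = "complete") {
  clusterProfiles(binProfiles(enzExpr, nBins = nBins), enzExpr,
                  nClusters = nClusters, distance = distance,
                  linkage = linkage)
}

#' Select the number of clusters by core-list stability
#'
#' As the cluster count N grows, weak clusters break apart while strong ones
#' persist, and the per-context core reaction lists stabilise. For every N in
#' \code{nRange} this computes core lists at N and N + 1 and records their
#' mean (over contexts) Jaccard similarity; the chosen N is the smallest one
#' whose similarity exceeds \code{jaccardCut} and stays above it for all
#' larger tested N. If no N qualifies, the range maximum is returned with
#' \code{warning = TRUE}.
#'
#' @param enzExpr an [EnzymeExpression-class] or numeric matrix.
#' @param catalog a [ReactionCatalog-class].
#' @param nRange integer vector of length 2, the inclusive N range to scan
#'   (must lie within [2, enzymes - 1]).
#' @param jaccardCut similarity cut, default 0.90.
#' @param nBins,distance,linkage clustering parameters, see
#'   [clusterEnzymes()].
#' @param protected reaction ids always added to each core list.
#' @param coreFun optional function \code{(enzExpr, clustering, catalog,
#'   protected) -> CoreReactionSets} used to derive core lists; defaults to
#'   the cluster-specific thresholding pipeline
#'   ([standepThresholds()] + [standepCore()]).
#' @return list with elements \code{n} (chosen N), \code{trace} (data.frame
#'   of N and mean Jaccard similarity to N + 1) and \code{warning}.
#' @export
selectClusterCount <- function(enzExpr, catalog, nRange = c(2L, 10L),
                               jaccardCut = 0.90, nBins = 60L,
                               distance = "euclidean", linkage = "complete",
                               protected = character(), coreFun = NULL) {
  m <- .enzymeMatrix(enzExpr)
  nRange <- as.integer(nRange)
  if (length(nRange) != 2L || nRange[1] > nRange[2])
    stop("nRange must be c(min, max) with min <= max")
  if (nRange[1] < 2L || nRange[2] > nrow(m) - 1L)
    stop("nRange must lie within [2, enzymes - 1]")
  if (is.null(coreFun))
    coreFun <- function(enzExpr, clustering, catalog, protected) {
      th <- standepThresholds(clustering, enzExpr)
      standepCore(enzExpr, clustering, th, catalog, protected = protected,
                  keepProvenance = FALSE)
    }

  profiles <- binProfiles(m, nBins = nBins)
  ns <- nRange[1]:nRange[2]
  coreAt <- function(N) {
    cl <- clusterProfiles(profiles, m, nClusters = N,
                          distance = distance, linkage = linkage)
    coreSets(coreFun(m, cl, catalog, protected))
  }
  cores <- lapply(c(ns, nRange[2] + 1L), coreAt)
  sims <- vapply(seq_along(ns), function(i) {
    a <- cores[[i]]; b <- cores[[i + 1L]]
    mean(vapply(names(a), function(ctx) jaccardIndex(a[[ctx]], b[[ctx]]),
                numeric(1)))
  }, numeric(1))

  ok <- rev(cumprod(rev(sims > jaccardCut))) > 0  # above cut from here on
  if (any(ok)) {
    list(n = ns[which(ok)[1]],
         trace = data.frame(n = ns, similarity = sims),
         warning = FALSE)
  } else {
    warning("no cluster count reached a Jaccard similarity of ", jaccardCut,
            "; returning the range maximum")
    list(n = nRange[2], trace = data.frame(n = ns, similarity = sims),
         warning = TRUE)
  }
}
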