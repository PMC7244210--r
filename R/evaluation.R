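## Evaluation statistics: Jaccard similarity, housekeeping coverage,
## hypergeometric cluster enrichment with BH-FDR, self-consistency and
## Gini-coefficient housekeeping classification.

#' Jaccard similarity of two identifier sets
#'
#' Intersection over union. Two empty sets have identical contents and score
#' 1 by convention (relevant when comparing very small models).
#'
#' @param a,b character vectors (treated as sets).
#' @return fraction in [0, 1].
#' @examples
#' jaccardIndex(c("a", "b"), c("b", "c"))  # 1/3
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise Jaccard similarity matrix
#'
#' Jaccard similarity of reaction (or gene) content between every pair of
#' models or core sets, e.g. for clustering model content across contexts.
#'
#' @param sets named list of character vectors.
#' @return symmetric numeric matrix.
#' @export
jaccardMatrix <- function(sets) {
  n <- length(sets)
  out <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <- jaccardIndex(sets[[i]], sets[[j]])
  }
  out
}

#' Coverage of a reference set by per-context core sets or models
#'
#' Per context, the fraction of a reference list (e.g. housekeeping
#' reactions) present in that context's set; the mean across contexts is the
#' headline statistic.
#'
#' @param sets a [CoreReactionSets-class] or named list of character vectors.
#' @param reference non-empty character vector of reference identifiers.
#' @return list with \code{perContext} (named fractions), \code{mean} and
#'   \code{denominator} (the reference size used for normalisation).
#' @export
housekeepingCoverage <- function(sets, reference) {
  if (is(sets, "CoreReactionSets")) sets <- coreSets(sets)
  reference <- unique(as.character(reference))
  if (!length(reference)) stop("reference set is empty")
  frac <- vapply(sets, function(s)
    length(intersect(s, reference)) / length(reference), numeric(1))
  list(perContext = frac, mean = mean(frac), denominator = length(reference))
}

#' Housekeeping enrichment of clusters
#'
#' For every cluster, tests over-representation of housekeeping reactions
#' among the reactions its enzymes catalyze: the upper-tail hypergeometric
#' probability of observing at least the seen count, given the population of
#' all reactions carried by clustered enzymes. P-values are
#' Benjamini-Hochberg corrected across clusters. Because a reaction's
#' isoenzymes may sit in different clusters, a reaction can count in several
#' clusters; membership is attributed per enzyme.
#'
#' @param clustering a [ClusteringResult-class].
#' @param hkReactions character vector of housekeeping reaction ids.
#' @param catalog a [ReactionCatalog-class].
#' @param alpha FDR level for the \code{enriched} flag (default 0.05).
#' @return data.frame with one row per cluster: \code{cluster},
#'   \code{hk_count}, \code{cluster_size}, \code{population_size},
#'   \code{population_hk}, \code{p}, \code{q}, \code{enriched}.
#' @export
clusterEnrichment <- function(clustering, hkReactions, catalog,
                              alpha = 0.05) {
  a <- clusterAssignment(clustering)
  e2r <- .enzymeToReactions(catalog)
  clustered <- intersect(names(a), names(e2r))
  population <- unique(unlist(e2r[clustered], use.names = FALSE))
  hk <- intersect(unique(as.character(hkReactions)), population)
  K <- length(hk)
  N <- length(population)
  rows <- lapply(sort(unique(a)), function(k) {
    enz <- intersect(names(a)[a == k], names(e2r))
    rxns <- unique(unlist(e2r[enz], use.names = FALSE))
    n <- length(rxns)
    x <- length(intersect(rxns, hk))
    p <- if (n == 0) 1 else
      stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(cluster = k, hk_count = x, cluster_size = n,
               population_size = N, population_hk = K, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q <= alpha
  out
}

#' Self-consistency of extracted models against their core lists
#'
#' A model-extraction method is self-consistent when it adds few reactions
#' beyond the expression-supported core. Per context this reports the
#' fraction of model reactions present in the core list, plus the Jaccard
#' similarity of the two sets.
#'
#' @param core a [CoreReactionSets-class] or named list (context -> ids).
#' @param modelSets named list (context -> model reaction ids), context ids
#'   matching \code{core}.
#' @return data.frame with columns \code{context}, \code{fraction_in_core},
#'   \code{jaccard}.
#' @export
selfConsistency <- function(core, modelSets) {
  if (is(core, "CoreReactionSets")) core <- coreSets(core)
  ctxs <- intersect(names(core), names(modelSets))
  if (!length(ctxs)) stop("no shared context identifiers")
  rows <- lapply(ctxs, function(ctx) {
    mod <- unique(modelSets[[ctx]])
    if (!length(mod)) stop("empty model set for context ", ctx)
    data.frame(context = ctx,
               fraction_in_core = length(intersect(mod, core[[ctx]])) /
                 length(mod),
               jaccard = jaccardIndex(mod, core[[ctx]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalized Gini coefficients of expression across contexts
#'
#' The Gini coefficient of a gene's expression vector measures how unequally
#' it is expressed across contexts: 0 for perfectly even expression, 1 (after
#' the small-sample normalization by n/(n-1)) for expression confined to a
#' single context. Computed on the linear expression scale; all-zero genes
#' are undefined and excluded.
#'
#' @param expr numeric genes-by-contexts matrix (>= 2 contexts).
#' @return named numeric vector of normalized Gini coefficients; excluded
#'   gene ids are attached as attribute \code{"excluded"}.
#' @export
giniCoefficients <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 2)
    stop("need a matrix with at least two contexts")
  if (any(expr < 0)) stop("expression must be nonnegative")
  n <- ncol(expr)
  tot <- rowSums(expr)
  excluded <- rownames(expr)[tot == 0]
  keep <- tot > 0
  g <- apply(expr[keep, , drop = FALSE], 1, function(x) {
    xs <- sort(x)
    sum((2 * seq_len(n) - n - 1) * xs) / (n * sum(xs))
  })
  g <- g * n / (n - 1)
  attr(g, "excluded") <- excluded
  g
}

#' Classify housekeeping genes by Gini coefficient
#'
#' Genes whose normalized Gini coefficient is at or below \code{cutoff} are
#' classified housekeeping (evenly expressed across contexts). The default
#' cutoff of 0.24 is the value at which housekeeping calls from two large
#' independent expression compendia best agree.
#'
#' @inheritParams giniCoefficients
#' @param cutoff classification cutoff on the normalized Gini coefficient
#'   (default 0.24).
#' @return list with \code{gini} (named vector), \code{housekeeping}
#'   (gene ids with gini <= cutoff), \code{excluded} (all-zero genes) and
#'   \code{cutoff}.
#' @export
giniHousekeeping <- function(expr, cutoff = 0.24) {
  g <- giniCoefficients(expr)
  list(gini = g,
       housekeeping = names(g)[g <= cutoff],
       excluded = attr(g, "excluded"),
       cutoff = cutoff)
}
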