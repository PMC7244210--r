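## Shared numeric helpers.

#' Resolve a "top X percentile" cutoff
#'
#' The cutoff above which values lie in the top \code{topPercentile} percent
#' of the data: the quantile at probability \code{(100 - topPercentile)/100},
#' with linear interpolation between order statistics
#' (\code{stats::quantile} type 7). Activity calls throughout the package
#' use a strict \code{>} against this cutoff.
#'
#' @param values numeric vector (must be non-empty).
#' @param topPercentile percentage in [0, 100]; e.g. 25 selects the top
#'   quarter of the data.
#' @return the cutoff value.
#' @examples
#' topPercentileCutoff(1:100, 25)  # 75th-percentile value
#' @export
topPercentileCutoff <- function(values, topPercentile) {
  if (!length(values)) stop("cannot take a percentile of an empty set")
  if (topPercentile < 0 || topPercentile > 100)
    stop("topPercentile must lie in [0, 100]")
  stats::quantile(values, probs = (100 - topPercentile) / 100,
                  names = FALSE, type = 7)
}

## Coerce EnzymeExpression or a plain enzymes-by-contexts matrix.
.enzymeMatrix <- function(x) {
  if (is(x, "EnzymeExpression")) return(x@values)
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("enzyme matrix must carry enzyme rownames and context colnames")
    return(x)
  }
  stop("expected an EnzymeExpression or a numeric enzymes-by-contexts matrix")
}

## log10 with zeros mapped to -Inf (zeros are 'not expressed', never active).
.log10OrNegInf <- function(m) {
  out <- suppressWarnings(log10(m))
  out[m <= 0] <- -Inf
  out
}

## All positive values of a matrix on the log10 scale.
.pooledLog10 <- function(m) {
  v <- m[m > 0]
  if (!length(v)) stop("matrix contains no positive values")
  log10(v)
}

## Map enzyme id -> reactions it catalyzes.
.enzymeToReactions <- function(catalog) {
  re <- catalog@rxnEnzymes
  n <- lengths(re)
  df <- data.frame(reaction = rep(names(re), n),
                   enzyme = unlist(re, use.names = FALSE),
                   stringsAsFactors = FALSE)
  split(df$reaction, df$enzyme)
}

## Per-enzyme cluster index aligned to the rows of an enzyme matrix.
.alignedClusters <- function(mat, clustering) {
  a <- clustering@assignment
  missing <- setdiff(rownames(mat), names(a))
  if (length(missing))
    stop("enzymes without a cluster assignment: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  unname(a[rownames(mat)])
}
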