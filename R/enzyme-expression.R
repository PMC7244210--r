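## Gene expression -> enzyme expression (minimum over AND-clause genes).

#' Read a genes-by-contexts expression matrix from delimited text
#'
#' Expects the first column to hold gene identifiers and the header row to
#' hold context identifiers; the separator is sniffed by
#' \code{data.table::fread}, and gzip-compressed files are accepted.
#' Duplicate gene rows are kept as-is here and reduced (by max) during
#' mapping in [computeEnzymeExpression()].
#'
#' @param path path to the delimited file.
#' @return numeric matrix with gene rownames and context colnames.
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("expression file needs a gene column plus contexts")
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(!is.finite(m)) || any(m < 0))
    stop("expression values must be finite and nonnegative")
  m
}

#' Write an enzymes-by-contexts matrix as delimited text
#'
#' @param x an [EnzymeExpression-class] or numeric matrix.
#' @param path output path (tab-separated; first column \code{enzyme_id}).
#' @return the path, invisibly.
#' @export
writeEnzymeExpression <- function(x, path) {
  m <- .enzymeMatrix(x)
  df <- data.frame(enzyme_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute enzyme expression from gene expression and a catalog
#'
#' Each enzyme (one AND-clause of a GPR) receives, in every context, the
#' minimum expression among its genes: the least expressed subunit governs
#' how much functional enzyme can form. Single-gene enzymes inherit the gene
#' value unchanged. Zeros propagate through the minimum (a complex with an
#' unexpressed subunit is unexpressed).
#'
#' Duplicate gene rows in the expression matrix are reduced by their
#' elementwise maximum before mapping. Genes in the catalog but absent from
#' the expression data are reported; by default any enzyme touching such a
#' gene is dropped (\code{"drop"}), or missing genes can be treated as zero
#' expression (\code{"zero"}), which zeroes the whole enzyme.
#'
#' @param expr numeric genes-by-contexts matrix (gene rownames, context
#'   colnames), e.g. from [readExpressionMatrix()].
#' @param catalog a [ReactionCatalog-class].
#' @param missingGenePolicy \code{"drop"} (default) or \code{"zero"}.
#' @return an [EnzymeExpression-class]; dropped enzymes and genes are
#'   recorded in its slots (see [droppedEnzymes()], [droppedGenes()]).
#' @examples
#' cat <- buildReactionCatalog(data.frame(reaction_id = "R1",
#'                                        gpr = "g1 and g2"))
#' expr <- matrix(c(5, 3), 2, 1, dimnames = list(c("g1", "g2"), "ctx1"))
#' exprValues(computeEnzymeExpression(expr, cat))  # min(5, 3) = 3
#' @export
computeEnzymeExpression <- function(expr, catalog,
                                    missingGenePolicy = c("drop", "zero")) {
  missingGenePolicy <- match.arg(missingGenePolicy)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr must carry gene rownames and context colnames")
  if (any(expr < 0)) stop("expression values must be nonnegative")

  rn <- rownames(expr)
  if (anyDuplicated(rn)) {
    ug <- unique(rn)
    expr <- t(vapply(ug, function(g) {
      apply(expr[rn == g, , drop = FALSE], 2, max)
    }, numeric(ncol(expr))))
    rownames(expr) <- ug
  }

  genes <- catalogGenes(catalog)
  present <- intersect(genes, rownames(expr))
  if (!length(present))
    stop("no overlap between catalog genes and expression matrix rows")
  absent <- setdiff(genes, rownames(expr))

  enz <- catalog@enzymes
  hasMissing <- vapply(enz, function(g) any(!(g %in% rownames(expr))),
                       logical(1))
  if (missingGenePolicy == "drop") {
    keep <- names(enz)[!hasMissing]
    droppedEnz <- names(enz)[hasMissing]
  } else {
    keep <- names(enz)
    droppedEnz <- character(0)
  }
  if (!length(keep))
    stop("every enzyme lost a gene to the expression data; nothing to map")

  vals <- matrix(0, nrow = length(keep), ncol = ncol(expr),
                 dimnames = list(keep, colnames(expr)))
  for (i in seq_along(keep)) {
    g <- enz[[keep[i]]]
    g_in <- g[g %in% rownames(expr)]
    if (length(g_in) < length(g)) {
      ## policy "zero": a missing gene contributes 0 to the minimum
      vals[i, ] <- 0
    } else if (length(g_in) == 1L) {
      vals[i, ] <- expr[g_in, ]
    } else {
      vals[i, ] <- apply(expr[g_in, , drop = FALSE], 2, min)
    }
  }
  new("EnzymeExpression", values = vals,
      droppedEnzymes = droppedEnz, droppedGenes = absent)
}

#' Combine enzyme expression per reaction
#'
#' Collapses isoenzyme expression to one value per reaction: the maximum
#' (default; any functional isoenzyme suffices) or the sum over the
#' reaction's enzymes. Gene-free reactions, and reactions whose enzymes were
#' all dropped during gene matching, carry \code{NA} as a no-data sentinel.
#'
#' @param enzExpr an [EnzymeExpression-class] or numeric matrix.
#' @param catalog a [ReactionCatalog-class].
#' @param combine \code{"max"} or \code{"sum"}.
#' @return numeric reactions-by-contexts matrix with \code{NA} for no-data
#'   reactions.
#' @export
reactionExpression <- function(enzExpr, catalog, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  m <- .enzymeMatrix(enzExpr)
  rids <- reactionIds(catalog)
  out <- matrix(NA_real_, nrow = length(rids), ncol = ncol(m),
                dimnames = list(rids, colnames(m)))
  fun <- if (combine == "max") function(x) apply(x, 2, max) else colSums
  for (rid in rids) {
    eids <- intersect(catalog@rxnEnzymes[[rid]], rownames(m))
    if (!length(eids)) next
    out[rid, ] <- fun(m[eids, , drop = FALSE])
  }
  out
}
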