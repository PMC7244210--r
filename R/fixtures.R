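## Synthetic fixtures: multi-context expression matrices with planted
## expression-pattern clusters and a toy reaction catalog with AND-complexes,
## isoenzymes and gene-free reactions. Everything downstream of the package
## is testable on these without any external download.

#' Specification of a synthetic fixture
#'
#' Defines planted clusters of genes whose log10 expression is drawn
#' i.i.d. per context from a Normal with the cluster's mean and sd, with
#' dropout (a value set to zero, "not expressed") at the stated rate, plus
#' the shape of a toy reaction catalog wired onto those genes.
#'
#' The default plants four clusters over 40 contexts, emulating the
#' structure that distinguishes cluster-specific from global thresholding:
#' a low-mean, low-sd "housekeeping-like" cluster about one decade below the
#' dataset mean; a slightly lower and sparser low-expression cluster; and
#' two well-separated moderately/highly expressed clusters of increasing
#' spread. Defaults for the catalog: 300 reactions of which 20 percent are
#' AND-complexes (complex subunits drawn within one planted cluster),
#' 15 percent isoenzyme pairs, and 5 percent gene-free.
#'
#' Subunit genes of one complex are co-expressed: they share a per-context
#' latent profile plus small independent log10 noise
#' (\code{complexCoexSD}), reflecting the co-regulation of complex members.
#' Without this, the minimum over independent subunits would shift every
#' complex systematically below its cluster, making the planted labels
#' meaningless for AND enzymes.
#'
#' @param nContexts number of contexts (samples); default 40.
#' @param clusters data.frame with columns \code{n_genes},
#'   \code{mean_log10}, \code{sd_log10}, \code{dropout}; one row per planted
#'   cluster.
#' @param nReactions,fracAnd,fracIso,fracGeneFree catalog shape.
#' @param complexCoexSD log10 sd of subunit noise around the shared complex
#'   profile (default 0.05).
#' @param hkClusters indices of clusters whose genes form the housekeeping
#'   reference (default 1).
#' @param seed integer seed; a fixed seed makes [generateFixture()] output
#'   byte-identical across calls.
#' @return a list of class \code{"fixtureSpec"}.
#' @export
fixtureSpec <- function(nContexts = 40L,
                        clusters = data.frame(
                          n_genes = c(50L, 50L, 50L, 50L),
                          mean_log10 = c(-0.3, -0.6, 1.5, 3.0),
                          sd_log10 = c(0.10, 0.12, 0.20, 0.80),
                          dropout = c(0.00, 0.20, 0.05, 0.02)),
                        nReactions = 300L, fracAnd = 0.20, fracIso = 0.15,
                        fracGeneFree = 0.05, complexCoexSD = 0.05,
                        hkClusters = 1L, seed = 1L) {
  stopifnot(nContexts >= 2L, is.data.frame(clusters),
            all(c("n_genes", "mean_log10", "sd_log10", "dropout") %in%
                  names(clusters)))
  if (any(clusters$n_genes < 1L))
    stop("every planted cluster needs at least one gene")
  if (any(clusters$dropout < 0 | clusters$dropout > 1))
    stop("dropout rates must lie in [0, 1]")
  fr <- c(fracAnd, fracIso, fracGeneFree)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("catalog fractions must lie in [0, 1] and sum to at most 1")
  if (any(hkClusters < 1L | hkClusters > nrow(clusters)))
    stop("hkClusters out of range")
  structure(list(nContexts = as.integer(nContexts), clusters = clusters,
                 nReactions = as.integer(nReactions), fracAnd = fracAnd,
                 fracIso = fracIso, fracGeneFree = fracGeneFree,
                 complexCoexSD = complexCoexSD,
                 hkClusters = as.integer(hkClusters),
                 seed = as.integer(seed)),
            class = "fixtureSpec")
}

#' Generate a synthetic expression matrix and reaction catalog
#'
#' Draws the planted expression matrix and wires a toy catalog according to
#' a [fixtureSpec()]. The RNG state is saved and restored, so the fixture is
#' reproducible from its seed and leaves the caller's RNG untouched.
#'
#' @param spec a [fixtureSpec()] (defaults apply when omitted).
#' @return list with elements:
#' \describe{
#'   \item{expression}{genes-by-contexts linear-scale matrix with dropout
#'     zeros.}
#'   \item{catalog}{a [ReactionCatalog-class].}
#'   \item{geneClusters}{named integer, planted cluster per gene.}
#'   \item{enzymeClusters}{named integer, planted cluster per catalog
#'     enzyme (AND-complex subunits are drawn within one cluster, so the
#'     label is well defined).}
#'   \item{hkGenes, hkReactions}{the housekeeping reference: genes of the
#'     flagged clusters and reactions catalyzed by at least one enzyme made
#'     entirely of those genes.}
#'   \item{spec}{the spec used.}
#' }
#' @export
generateFixture <- function(spec = fixtureSpec()) {
  if (!inherits(spec, "fixtureSpec")) stop("spec must come from fixtureSpec()")
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec$seed)

  cl <- spec$clusters
  nGenes <- sum(cl$n_genes)
  geneClusters <- rep(seq_len(nrow(cl)), cl$n_genes)
  genes <- sprintf("c%d_g%03d", geneClusters,
                   unlist(lapply(cl$n_genes, seq_len)))
  names(geneClusters) <- genes

  ## Partition the head of each cluster's gene list into co-expressed
  ## complex groups of size 2-3; the rest are independently expressed.
  complexGroups <- list()
  groupOf <- stats::setNames(rep(NA_integer_, nGenes), genes)
  for (k in seq_len(nrow(cl))) {
    gk <- genes[geneClusters == k]
    nGrp <- cl$n_genes[k] %/% 4L
    i <- 1L
    for (g in seq_len(nGrp)) {
      sz <- sample(2:3, 1L)
      if (i + sz - 1L > length(gk)) break
      members <- gk[i:(i + sz - 1L)]
      complexGroups[[length(complexGroups) + 1L]] <- members
      groupOf[members] <- length(complexGroups)
      i <- i + sz
    }
  }

  ctxs <- sprintf("ctx%02d", seq_len(spec$nContexts))
  ## Shared latent per-context profile for each complex group.
  latent <- lapply(complexGroups, function(members) {
    k <- geneClusters[[members[1]]]
    stats::rnorm(spec$nContexts, cl$mean_log10[k], cl$sd_log10[k])
  })
  expr <- matrix(0, nrow = nGenes, ncol = spec$nContexts,
                 dimnames = list(genes, ctxs))
  for (i in seq_len(nGenes)) {
    k <- geneClusters[i]
    lv <- if (is.na(groupOf[i]))
      stats::rnorm(spec$nContexts, cl$mean_log10[k], cl$sd_log10[k])
    else
      latent[[groupOf[i]]] + stats::rnorm(spec$nContexts, 0,
                                          spec$complexCoexSD)
    v <- 10^lv
    v[stats::runif(spec$nContexts) < cl$dropout[k]] <- 0
    expr[i, ] <- v
  }

  nR <- spec$nReactions
  nGF <- round(spec$fracGeneFree * nR)
  nAND <- round(spec$fracAnd * nR)
  nISO <- round(spec$fracIso * nR)
  nSingle <- nR - nGF - nAND - nISO
  if (nSingle < 0) stop("catalog fractions leave no single-enzyme reactions")
  if (nAND > 0 && !length(complexGroups))
    stop("clusters too small to form any complex group")
  kind <- sample(rep(c("single", "and", "iso", "free"),
                     c(nSingle, nAND, nISO, nGF)))
  gpr <- character(nR)
  for (i in seq_len(nR)) {
    gpr[i] <- switch(kind[i],
      single = sample(genes, 1L),
      and = paste(complexGroups[[sample(length(complexGroups), 1L)]],
                  collapse = " and "),
      iso = paste(sample(genes, 2L), collapse = " or "),
      free = "")
  }
  catalog <- buildReactionCatalog(
    data.frame(reaction_id = sprintf("R%04d", seq_len(nR)), gpr = gpr,
               subsystem = paste0("pathway_", kind), stringsAsFactors = FALSE))

  enzymeClusters <- vapply(enzymeGenes(catalog), function(g)
    geneClusters[[g[1]]], integer(1))

  hkGenes <- genes[geneClusters %in% spec$hkClusters]
  hkEnzymes <- names(enzymeClusters)[enzymeClusters %in% spec$hkClusters]
  e2r <- .enzymeToReactions(catalog)
  hkReactions <- sort(unique(unlist(e2r[intersect(hkEnzymes, names(e2r))],
                                    use.names = FALSE)))

  list(expression = expr, catalog = catalog, geneClusters = geneClusters,
       enzymeClusters = enzymeClusters, hkGenes = hkGenes,
       hkReactions = if (is.null(hkReactions)) character(0) else hkReactions,
       spec = spec)
}

#' Write a fixture to disk in pipeline-consumable formats
#'
#' Expression as TSV (first column \code{gene_id}), catalog as the JSON model
#' dialect, housekeeping references as one-id-per-line text files, planted
#' labels as TSV.
#'
#' @param fixture result of [generateFixture()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- data.frame(gene_id = rownames(fixture$expression),
                     fixture$expression, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat <- fixture$catalog
  rxns <- lapply(seq_len(nrow(cat@reactions)), function(i) {
    rid <- cat@reactions$reaction_id[i]
    eids <- cat@rxnEnzymes[[rid]]
    rule <- paste(vapply(cat@enzymes[eids], function(g)
      if (length(g) > 1) paste0("(", paste(g, collapse = " and "), ")")
      else g, character(1)), collapse = " or ")
    list(id = rid, subsystem = cat@reactions$subsystem[i],
         gene_reaction_rule = rule)
  })
  jsonlite::write_json(list(id = "synthetic_toy_model", reactions = rxns),
                       file.path(dir, "model.json"), auto_unbox = TRUE)
  writeLines(fixture$hkGenes, file.path(dir, "hk_genes.txt"))
  writeLines(fixture$hkReactions, file.path(dir, "hk_reactions.txt"))
  utils::write.table(
    data.frame(gene_id = names(fixture$geneClusters),
               cluster = fixture$geneClusters),
    file.path(dir, "planted_gene_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
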