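# Small in-code fixtures shared across test files.

# Catalog with an AND complex, isoenzymes, shared enzymes and a gene-free
# reaction.
toy_catalog <- function() {
  buildReactionCatalog(data.frame(
    reaction_id = c("R1", "R2", "R3", "R4", "R5"),
    gpr = c("g1 and g2",            # complex
            "g1 or (g2 and g3)",    # isoenzymes, nested
            "g4",                   # single gene
            "g4",                   # shares the enzyme of R3
            ""),                    # gene-free
    subsystem = c("glycolysis", "glycolysis", "tca", "tca", "transport")))
}

# Deterministic small expression matrix over the toy catalog's genes.
toy_expression <- function() {
  m <- rbind(g1 = c(5, 1, 0),
             g2 = c(3, 8, 6),
             g3 = c(0, 4, 2),
             g4 = c(2, 0, 6))
  colnames(m) <- c("s1", "s2", "s3")
  m
}

# Random enzyme-expression matrix plus a matching single-gene catalog; used
# by the equation-oracle tests. Each enzyme is its own gene so the catalog
# wiring stays trivial and the numeric path is fully exercised.
random_instance <- function(seed, nEnzymes = 20L, nContexts = 6L,
                            nClusters = 3L, dropout = 0.15) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(nEnzymes))
  mat <- matrix(10^rnorm(nEnzymes * nContexts, mean = 1, sd = 1.2),
                nrow = nEnzymes,
                dimnames = list(genes, sprintf("s%02d", seq_len(nContexts))))
  mat[runif(length(mat)) < dropout] <- 0
  # ensure every enzyme keeps at least one positive value
  for (i in seq_len(nEnzymes)) if (all(mat[i, ] == 0)) mat[i, 1] <- 10^rnorm(1)
  catalog <- buildReactionCatalog(data.frame(
    reaction_id = sprintf("R%03d", seq_len(nEnzymes)), gpr = genes))
  assignment <- setNames(sample(seq_len(nClusters), nEnzymes, replace = TRUE),
                         genes)
  # guarantee every cluster is populated
  assignment[seq_len(nClusters)] <- seq_len(nClusters)
  list(mat = mat, catalog = catalog, assignment = assignment,
       nClusters = nClusters)
}

# Build a ClusteringResult from a forced assignment (bypassing the tree) so
# threshold math can be tested against arbitrary partitions.
forced_clustering <- function(mat, assignment, nClusters) {
  standep:::.clusteringFromAssignment(mat, assignment, nClusters,
                                      distance = "euclidean",
                                      linkage = "complete")
}
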