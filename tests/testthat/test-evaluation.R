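test_that("Jaccard similarity behaves as a set metric", {
  expect_equal(jaccardIndex(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccardIndex(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccardIndex(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccardIndex(character(0), character(0)), 1)  # convention
  # symmetry and bounds on random sets
  set.seed(2)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    expect_equal(jaccardIndex(a, b), jaccardIndex(b, a))
    expect_true(jaccardIndex(a, b) >= 0 && jaccardIndex(a, b) <= 1)
    if (length(a) && jaccardIndex(a, b) == 1) expect_setequal(a, b)
  }
  jm <- jaccardMatrix(list(x = c("a", "b"), y = c("b", "c"), z = "d"))
  expect_equal(jm, t(jm))
  expect_equal(diag(jm), c(x = 1, y = 1, z = 1))
})

test_that("housekeeping coverage divides by the reference size", {
  sets <- list(s1 = c("a", "b", "c"), s2 = c("x"), s3 = letters[1:10])
  ref <- letters[1:10]
  cov <- housekeepingCoverage(sets, ref)
  expect_equal(unname(cov$perContext), c(3 / 10, 0, 1))
  expect_equal(cov$mean, mean(c(0.3, 0, 1)))
  expect_equal(cov$denominator, 10)
  expect_error(housekeepingCoverage(sets, character(0)), "empty")
})

test_that("cluster enrichment matches exact hypergeometric enumeration", {
  # population of 20 single-gene reactions, 10 housekeeping
  genes <- sprintf("g%02d", 1:20)
  cat <- buildReactionCatalog(data.frame(reaction_id = toupper(genes),
                                         gpr = genes))
  hk <- toupper(genes[1:10])
  # cluster 1 holds the first 5 genes (all housekeeping)
  assignment <- setNames(c(rep(1L, 5), rep(2L, 15)), genes)
  cl <- new("ClusteringResult", nClusters = 2L, assignment = assignment,
            clusterStats = data.frame(cluster = 1:2,
                                      n_enzymes = c(5L, 15L),
                                      n_values = c(5L, 15L),
                                      mu = c(0, 1), sigma = c(0.1, 0.2)),
            datasetMean = 0.5, datasetSD = 0.5,
            distance = "euclidean", linkage = "complete")
  tab <- clusterEnrichment(cl, hk, cat)
  expect_equal(tab$p[1], oracle_hyper_upper(5, 10, 20, 5), tolerance = 1e-12)
  expect_equal(tab$p[2], oracle_hyper_upper(5, 10, 20, 15), tolerance = 1e-12)
  expect_equal(tab$q, p.adjust(tab$p, "BH"))
  expect_true(all(tab$q >= tab$p - 1e-15))
  # a cluster with zero housekeeping reactions has upper-tail p = 1 when
  # it could not have fewer
  assignment2 <- setNames(c(rep(1L, 10), rep(2L, 10)), genes)
  cl2 <- cl
  cl2@assignment <- assignment2
  tab2 <- clusterEnrichment(cl2, toupper(genes[11:20]), cat)
  expect_equal(tab2$hk_count[1], 0)
  expect_equal(tab2$p[1], 1)
})

test_that("BH correction is monotone across a random table", {
  genes <- sprintf("g%02d", 1:24)
  cat <- buildReactionCatalog(data.frame(reaction_id = toupper(genes),
                                         gpr = genes))
  set.seed(9)
  assignment <- setNames(sample(1:6, 24, replace = TRUE), genes)
  assignment[1:6] <- 1:6
  cl <- new("ClusteringResult", nClusters = 6L, assignment = assignment,
            clusterStats = data.frame(cluster = 1:6,
                                      n_enzymes = tabulate(assignment, 6),
                                      n_values = tabulate(assignment, 6),
                                      mu = rnorm(6), sigma = runif(6)),
            datasetMean = 0, datasetSD = 1,
            distance = "euclidean", linkage = "complete")
  tab <- clusterEnrichment(cl, toupper(sample(genes, 8)), cat)
  expect_true(all(diff(tab$q[order(tab$p)]) >= -1e-15))
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_true(all(tab$p >= 0 & tab$p <= 1 & tab$q >= 0 & tab$q <= 1))
})

test_that("self-consistency reports the fraction of model in core", {
  core <- list(s1 = c("a", "b", "c"), s2 = c("a"))
  models <- list(s1 = c("a", "b", "d", "e"), s2 = c("x", "y"))
  sc <- selfConsistency(core, models)
  expect_equal(sc$fraction_in_core, c(0.5, 0))
  expect_equal(sc$jaccard[1], 2 / 5)
  expect_error(selfConsistency(core, list(s1 = character(0))), "empty")
  # model contained in core
  sc2 <- selfConsistency(core, list(s1 = c("a", "b")))
  expect_equal(sc2$fraction_in_core, 1)
})

test_that("Gini coefficients match the pairwise-difference oracle", {
  n <- 6
  set.seed(4)
  expr <- rbind(flat = rep(3, n),
                onehot = c(rep(0, n - 1), 7),
                random1 = runif(n, 0, 10),
                random2 = rexp(n),
                allzero = rep(0, n))
  colnames(expr) <- sprintf("s%d", 1:n)
  g <- giniCoefficients(expr)
  expect_equal(unname(g["flat"]), 0)
  expect_equal(unname(g["onehot"]), 1)  # one-hot reaches the normalized max
  for (gene in c("random1", "random2"))
    expect_equal(unname(g[gene]), unname(oracle_gini(expr[gene, ])),
                 tolerance = 1e-12)
  expect_equal(attr(g, "excluded"), "allzero")
  # invariance to positive rescaling
  g2 <- giniCoefficients(expr[c("random1", "random2"), ] * 37.5)
  expect_equal(as.numeric(g2), as.numeric(g[c("random1", "random2")]))
  hk <- giniHousekeeping(expr, cutoff = 0.24)
  expect_true("flat" %in% hk$housekeeping)
  expect_false("onehot" %in% hk$housekeeping)
  expect_equal(hk$cutoff, 0.24)
  expect_error(giniCoefficients(expr[, 1, drop = FALSE]), "two contexts")
})
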