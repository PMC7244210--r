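test_that("raw thresholds follow the sigma and mean terms", {
  # hand-built clustering: cluster A(mu=2.0, sigma=1.0), B(mu=0.0,
  # sigma=0.5), dataset M=1.2, Delta=0.9; oracle evaluation of the formulas
  cl <- new("ClusteringResult", nClusters = 2L,
            assignment = c(e1 = 1L, e2 = 2L),
            clusterStats = data.frame(cluster = 1:2, n_enzymes = c(1L, 1L),
                                      n_values = c(5L, 5L),
                                      mu = c(2, 0), sigma = c(1, 0.5)),
            datasetMean = 1.2, datasetSD = 0.9,
            distance = "euclidean", linkage = "complete")
  theta <- rawClusterThresholds(cl)
  expected <- oracle_theta(mu = c(2, 0), sigma = c(1, 0.5),
                           M = 1.2, Delta = 0.9)
  expect_equal(unname(theta), expected, tolerance = 1e-12)
  # f = 1 and g = 0 when sigma_c attains the max and mu_c = M: theta = 1
  clM <- cl
  clM@clusterStats$mu[1] <- 1.2
  expect_equal(unname(rawClusterThresholds(clM))[1], 1)
  # raising a cluster's mean strictly lowers its threshold
  cl2 <- cl
  cl2@clusterStats$mu[2] <- 1.2
  expect_lt(rawClusterThresholds(cl2)[2], theta[2])
})

test_that("degenerate sigma terms are handled with warnings", {
  cl <- new("ClusteringResult", nClusters = 2L,
            assignment = c(e1 = 1L, e2 = 2L),
            clusterStats = data.frame(cluster = 1:2, n_enzymes = c(1L, 1L),
                                      n_values = c(5L, 5L),
                                      mu = c(1, 2), sigma = c(0.7, 0.7)),
            datasetMean = 1.5, datasetSD = 0.7,
            distance = "euclidean", linkage = "complete")
  expect_warning(theta <- rawClusterThresholds(cl), "zero")
  expect_equal(unname(theta), -(c(1, 2) - 1.5))  # f collapses to 0
  cl@datasetSD <- 0.9  # every cluster tighter than the dataset
  expect_warning(rawClusterThresholds(cl), "tighter")
})

test_that("normalisation maps thresholds onto [0, 100] affinely", {
  expect_equal(unname(normalizeThresholds(c(1, 3))), c(0, 100))
  expect_equal(unname(normalizeThresholds(c(1, 2, 3))), c(0, 50, 100))
  # permutation equivariance
  theta <- c(0.4, -1.2, 2.2, 0.9)
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(normalizeThresholds(theta)[perm]),
               unname(normalizeThresholds(theta[perm])))
  expect_warning(out <- normalizeThresholds(c(2, 2, 2)), "identical")
  expect_equal(unname(out), c(100, 100, 100))
  expect_error(normalizeThresholds(5), "two clusters")
})

test_that("cutoff resolution matches the quantile oracle and special case", {
  inst <- random_instance(99)
  cl <- forced_clustering(inst$mat, inst$assignment, inst$nClusters)
  thetaN <- c(25, 100, 0)
  ts <- resolveCutoffs(thetaN, cl, inst$mat)
  # Theta = 100 resolves to the dataset mean with the flag set
  expect_equal(cutoffValues(ts)[2], datasetStats(cl)$M)
  expect_true(specialMeanFlag(ts)[2])
  # Theta = 0 resolves to the cluster maximum
  vals3 <- log10(inst$mat[names(inst$assignment)[inst$assignment == 3], ])
  vals3 <- vals3[is.finite(vals3)]
  expect_equal(cutoffValues(ts)[3], max(vals3))
  # Theta = 25: top-25-percentile = oracle 75th percentile
  vals1 <- log10(inst$mat[names(inst$assignment)[inst$assignment == 1], ])
  vals1 <- vals1[is.finite(vals1)]
  expect_equal(cutoffValues(ts)[1], oracle_quantile(vals1, 0.75),
               tolerance = 1e-12)
  expect_error(resolveCutoffs(c(25, 100), cl, inst$mat), "per cluster")
})

test_that("cluster-specific cores activate strictly above the cutoff", {
  cat <- buildReactionCatalog(data.frame(
    reaction_id = c("RA", "RB", "RC"),
    gpr = c("e1", "e1 or e2", "e3")))
  m <- matrix(c(10, 0.1,   # e1
                0.1, 10,   # e2
                0, 0),     # e3: never expressed
              nrow = 3, byrow = TRUE,
              dimnames = list(c("e1", "e2", "e3"), c("s1", "s2")))
  cl <- forced_clustering(m, c(e1 = 1L, e2 = 1L, e3 = 2L), 2L)
  ts <- new("ThresholdSet", method = "standep", thetaRaw = numeric(2),
            thetaNorm = c(50, 50), cutoffs = c(0, 0),
            specialMean = c(FALSE, FALSE), params = list())
  core <- standepCore(m, cl, ts, cat, protected = "RC")
  sets <- coreSets(core)
  # e1 active only in s1 (10 > 1); isoenzyme rule keeps RB in both contexts
  expect_setequal(sets$s1, c("RA", "RB", "RC"))
  expect_setequal(sets$s2, c("RB", "RC"))  # via e2; RC only by protection
  # zero-expression enzymes never activate; RC is present by protection only
  expect_false("e3" %in% coreProvenance(core)$enzyme_id)
  expect_true(validObject(core))
})

test_that("global thresholding uses one top-percentile cutoff", {
  genes <- sprintf("e%02d", 1:10)
  cat <- buildReactionCatalog(data.frame(reaction_id = toupper(genes),
                                         gpr = genes))
  set.seed(42)
  m <- matrix(10^runif(40, -2, 2), nrow = 10,
              dimnames = list(genes, sprintf("s%d", 1:4)))
  core <- globalCore(m, cat, topPercentile = 25)
  cut <- oracle_top_percentile(log10(as.vector(m)), 25)
  for (ctx in colnames(m)) {
    expect_setequal(coreSets(core)[[ctx]],
                    toupper(genes[log10(m[, ctx]) > cut]))
  }
  # all-equal values: nothing strictly above the cutoff
  m2 <- matrix(5, 4, 2, dimnames = list(genes[1:4], c("s1", "s2")))
  core2 <- globalCore(m2, cat, topPercentile = 25)
  expect_true(all(lengths(coreSets(core2)) == 0))
})

test_that("localT1 variants disagree exactly as documented", {
  genes <- c("low", "mid")
  cat <- buildReactionCatalog(data.frame(reaction_id = c("RL", "RM"),
                                         gpr = genes))
  # "low" has small values everywhere; "mid" straddles its own mean
  m <- rbind(low = c(0.01, 0.02, 0.01, 0.02),
             mid = c(1, 9, 100, 1000))
  colnames(m) <- sprintf("s%d", 1:4)
  coreM <- localT1Core(m, cat, variant = "methods")
  # low's mean sits below the dataset 25th percentile: inactive everywhere
  expect_false(any(vapply(coreSets(coreM), function(s) "RL" %in% s,
                          logical(1))))
  # mid is active wherever it exceeds its own log-mean
  mu_mid <- mean(log10(m["mid", ]))
  expect_setequal(names(which(vapply(coreSets(coreM),
                                     function(s) "RM" %in% s, logical(1)))),
                  colnames(m)[log10(m["mid", ]) > mu_mid])
  # results variant: cutoff is max(own mean, dataset bound); low can pass
  coreR <- localT1Core(m, cat, variant = "results")
  bound <- oracle_top_percentile(log10(as.vector(m)), 75)
  cut_low <- max(mean(log10(m["low", ])), bound)
  expect_setequal(names(which(vapply(coreSets(coreR),
                                     function(s) "RL" %in% s, logical(1)))),
                  colnames(m)[log10(m["low", ]) > cut_low])
})

test_that("localT2 pins extremes and thresholds the mid-band at own mean", {
  genes <- c("hi", "low", "mid")
  cat <- buildReactionCatalog(data.frame(reaction_id = toupper(genes),
                                         gpr = genes))
  m <- rbind(hi = c(500, 800, 0, 900),    # high mean, one dropout context
             low = c(0.01, 0.02, 0.01, 0.02),
             mid = c(2, 8, 30, 90))
  colnames(m) <- sprintf("s%d", 1:4)
  core <- localT2Core(m, cat)
  inCore <- function(r) vapply(coreSets(core), function(s) r %in% s,
                               logical(1))
  # mean above the upper bound: active in all contexts, even the zero one
  expect_true(all(inCore("HI")))
  # mean below the lower bound: inactive everywhere
  expect_false(any(inCore("LOW")))
  # mid-band enzyme: active strictly above its own mean
  mu_mid <- mean(log10(m["mid", ]))
  expect_equal(unname(inCore("MID")), unname(log10(m["mid", ]) > mu_mid))
  expect_error(localT2Core(m, cat, upperTopPercentile = 75,
                           lowerTopPercentile = 25), "not below")
})

test_that("lowering a cluster's mean never shrinks its active calls", {
  # stats-level monotonicity: with all other cluster statistics held fixed,
  # lowering mu_1 raises theta_1, never lowers Theta_1, and the resolved
  # cutoff only moves down -- so the cluster's active set can only grow
  for (seed in 1:20) {
    inst <- random_instance(seed)
    cl <- forced_clustering(inst$mat, inst$assignment, inst$nClusters)
    cl2 <- cl
    cl2@clusterStats$mu[1] <- cl2@clusterStats$mu[1] - runif(1, 0.1, 1)
    t1 <- suppressWarnings(rawClusterThresholds(cl))
    t2 <- suppressWarnings(rawClusterThresholds(cl2))
    expect_gt(t2[["1"]], t1[["1"]])
    T1 <- suppressWarnings(normalizeThresholds(t1))
    T2 <- suppressWarnings(normalizeThresholds(t2))
    expect_gte(T2[["1"]], T1[["1"]] - 1e-9)
    ts1 <- resolveCutoffs(T1, cl, inst$mat)
    ts2 <- resolveCutoffs(T2, cl2, inst$mat)
    # both cutoffs are quantiles of the same member pool (unless the
    # dataset-mean special case triggers); a higher Theta cannot raise it
    if (!specialMeanFlag(ts1)[1] && !specialMeanFlag(ts2)[1])
      expect_lte(cutoffValues(ts2)[1], cutoffValues(ts1)[1] + 1e-9)
  }
})
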