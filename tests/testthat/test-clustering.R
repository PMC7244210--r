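test_that("binning counts contexts per log10 bin, excluding zeros", {
  # one value per decade over [0, 2]
  m <- matrix(c(1, 10, 100), nrow = 1,
              dimnames = list("e1", c("s1", "s2", "s3")))
  bp <- binProfiles(m, nBins = 3)
  expect_equal(unname(profileCounts(bp)[1, ]), c(1L, 1L, 1L))
  expect_equal(binEdges(bp), seq(0, 2, length.out = 4))

  # zeros are not counted anywhere
  m2 <- rbind(e1 = c(0, 0, 5), e2 = c(2, 3, 4))
  colnames(m2) <- c("s1", "s2", "s3")
  bp2 <- binProfiles(m2, nBins = 4)
  expect_equal(sum(profileCounts(bp2)["e1", ]), 1)
  expect_equal(sum(profileCounts(bp2)["e2", ]), 3)

  # identical value sets give identical rows
  m3 <- rbind(e1 = c(1, 5, 20), e2 = c(1, 5, 20), e3 = c(7, 8, 9))
  colnames(m3) <- c("s1", "s2", "s3")
  bp3 <- binProfiles(m3, nBins = 10)
  expect_equal(profileCounts(bp3)["e1", ], profileCounts(bp3)["e2", ],
               ignore_attr = TRUE)
  expect_error(binProfiles(matrix(0, 2, 2,
                                  dimnames = list(c("a", "b"), c("x", "y")))),
               "all zero")
  expect_true(validObject(bp3))
})

test_that("identical profiles co-cluster and stats live on log10 values", {
  m <- rbind(e1 = c(1, 5, 20), e2 = c(1, 5, 20), e3 = c(1000, 2000, 4000))
  colnames(m) <- c("s1", "s2", "s3")
  cl <- clusterEnzymes(m, nClusters = 2, nBins = 10)
  a <- clusterAssignment(cl)
  expect_equal(a[["e1"]], a[["e2"]])
  expect_true(a[["e3"]] != a[["e1"]])
  # dataset stats = moments of all positive log10 values
  expect_equal(datasetStats(cl)$M, mean(log10(m)))
  expect_equal(datasetStats(cl)$Delta, sd(log10(m)))
  # singleton clusters: sigma is that enzyme's own log10 sd
  clAll <- clusterEnzymes(m, nClusters = 3, nBins = 10)
  cs <- clusterStats(clAll)
  k3 <- clusterAssignment(clAll)[["e3"]]
  expect_equal(cs$sigma[cs$cluster == k3], sd(log10(m["e3", ])))
  expect_error(clusterEnzymes(m, nClusters = 0), "positive")
  expect_error(clusterEnzymes(m, nClusters = 9), "exceeds")
})

test_that("row order does not change cluster memberships", {
  fx <- generateFixture(fixtureSpec(seed = 5))
  enz <- exprValues(computeEnzymeExpression(fx$expression, fx$catalog))
  cl1 <- clusterEnzymes(enz, nClusters = 4)
  set.seed(1)
  perm <- sample(nrow(enz))
  cl2 <- clusterEnzymes(enz[perm, ], nClusters = 4)
  a1 <- clusterAssignment(cl1)
  a2 <- clusterAssignment(cl2)[names(a1)]
  # same partition up to relabeling
  expect_equal(mclust::adjustedRandIndex(a1, a2), 1)
  # dataset stats invariant to N
  cl3 <- clusterEnzymes(enz, nClusters = 7)
  expect_equal(datasetStats(cl1), datasetStats(cl3))
})

test_that("well-separated planted clusters are recovered exactly", {
  spec <- fixtureSpec(clusters = data.frame(
    n_genes = c(40L, 40L), mean_log10 = c(1.5, -0.5),
    sd_log10 = c(0.1, 0.1), dropout = c(0, 0)),
    nReactions = 100L, seed = 8)
  fx <- generateFixture(spec)
  enz <- computeEnzymeExpression(fx$expression, fx$catalog)
  cl <- clusterEnzymes(enz, nClusters = 2)
  labels <- fx$enzymeClusters[names(clusterAssignment(cl))]
  expect_equal(mclust::adjustedRandIndex(clusterAssignment(cl), labels), 1)
})

test_that("cluster-count selection applies the stability rule", {
  # synthetic traces through a stub core function are impractical; check the
  # rule arithmetic through the exported function on a tiny instance, and
  # the documented fallback behaviour
  fx <- generateFixture(fixtureSpec(clusters = data.frame(
    n_genes = c(30L, 30L), mean_log10 = c(1.5, -0.5),
    sd_log10 = c(0.1, 0.1), dropout = c(0, 0)),
    nReactions = 80L, seed = 8))
  enz <- computeEnzymeExpression(fx$expression, fx$catalog)
  sel <- suppressWarnings(selectClusterCount(enz, fx$catalog, nRange = c(2, 5)))
  expect_true(sel$n >= 2 && sel$n <= 5)
  expect_equal(nrow(sel$trace), 4)
  expect_true(all(sel$trace$similarity >= 0 & sel$trace$similarity <= 1))
  if (!sel$warning)
    expect_true(all(sel$trace$similarity[sel$trace$n >= sel$n] > 0.9))
  # unreachable cut falls back to the range maximum with a warning
  suppressWarnings(
    expect_warning(sel2 <- selectClusterCount(enz, fx$catalog,
                                              nRange = c(2, 4),
                                              jaccardCut = 1),
                   "maximum"))
  expect_equal(sel2$n, 4)
  expect_true(sel2$warning)
  expect_error(selectClusterCount(enz, fx$catalog, nRange = c(1, 4)),
               "within")
})
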