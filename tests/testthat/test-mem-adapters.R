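# Shared setup: a forced two-cluster instance with known cutoffs.
mem_instance <- function() {
  genes <- c("e1", "e2", "e3", "e4")
  cat <- buildReactionCatalog(data.frame(
    reaction_id = c("RA", "RB", "RC", "RD"),
    gpr = c("e1", "e2 or e3", "e4", "")))
  m <- rbind(e1 = c(100, 1),
             e2 = c(10, 0.1),
             e3 = c(0.1, 10),
             e4 = c(0, 1000))
  colnames(m) <- c("s1", "s2")
  cl <- forced_clustering(m, c(e1 = 1L, e2 = 1L, e3 = 2L, e4 = 2L), 2L)
  ts <- new("ThresholdSet", method = "standep", thetaRaw = numeric(2),
            thetaNorm = c(50, 50), cutoffs = c(1, 0),
            specialMean = c(FALSE, FALSE), params = list())
  list(cat = cat, m = m, cl = cl, ts = ts)
}

test_that("threshold distances are log10 gaps to the cluster cutoff", {
  mi <- mem_instance()
  D <- thresholdDistances(mi$m, mi$cl, mi$ts)
  # e1 in s1: log10(100) - 1 = 1 (one decade above)
  expect_equal(D["e1", "s1"], 1)
  # x exactly at the cutoff gives 0
  expect_equal(D["e2", "s1"], 0)
  # zero expression sits at the floor: log10(min positive) - 1 = -2
  expect_equal(D["e4", "s1"], log10(0.1) - 1 - 0)
  # elementwise oracle on a random instance
  inst <- random_instance(13)
  cl <- forced_clustering(inst$mat, inst$assignment, inst$nClusters)
  th <- suppressWarnings(standepThresholds(cl, inst$mat))
  D2 <- thresholdDistances(inst$mat, cl, th)
  ks <- sort(unique(inst$assignment))
  expect_equal(D2, oracle_distances(inst$mat, inst$assignment,
                                    cutoffValues(th), ks),
               tolerance = 1e-12)
})

test_that("ubiquity scores follow the piecewise rule with a global minimum", {
  mi <- mem_instance()
  D <- thresholdDistances(mi$m, mi$cl, mi$ts)
  U <- ubiquityScores(D, mi$cat, protected = character())
  # positive distance -> 1
  expect_equal(U["RA", "s1"], 1)
  # most negative distance anywhere -> 0
  mn <- min(D)
  eMin <- which(D == mn, arr.ind = TRUE)
  expect_true(all(abs(1 - D[eMin] / mn) < 1e-12))
  # gene-free reactions carry the sentinel
  expect_true(all(U["RD", ] == -1))
  # reaction score is the max over isoenzymes
  Ue <- oracle_ubiquity_enzyme(D)
  expect_equal(unname(U["RB", ]), unname(pmax(Ue["e2", ], Ue["e3", ])))
  # boundary D = 0 scores 1
  expect_equal(U["RB", "s1"], 1)
  # bounds on the gene-associated part
  expect_true(all(U[c("RA", "RB", "RC"), ] >= 0 & U[c("RA","RB","RC"), ] <= 1))
  # protected reactions are pinned to 1
  U2 <- ubiquityScores(D, mi$cat, protected = "RD")
  expect_true(all(U2["RD", ] == 1))
  # no negative distances anywhere: all ones plus a warning
  expect_warning(U3 <- ubiquityScores(abs(D) + 0.1, mi$cat), "no negative")
  expect_true(all(U3[c("RA", "RB", "RC"), ] == 1))
})

test_that("INIT weights scale by the maximum absolute distance and sum over
           isoenzymes", {
  mi <- mem_instance()
  D <- thresholdDistances(mi$m, mi$cl, mi$ts)
  W <- initWeights(D, mi$cat)
  mx <- max(abs(D))
  # single-enzyme reaction: the scaled distance itself, in [-1, 1]
  expect_equal(unname(W["RA", ]), unname(D["e1", ] / mx))
  # the globally most distant enzyme has weight magnitude 1
  expect_equal(max(abs(D / mx)), 1)
  # isoenzymes add
  expect_equal(unname(W["RB", ]), unname(D["e2", ] / mx + D["e3", ] / mx))
  # gene-free reactions weigh 0; protected weigh 1
  expect_true(all(W["RD", ] == 0))
  W2 <- initWeights(D, mi$cat, protected = "RA")
  expect_true(all(W2["RA", ] == 1))
  expect_warning(initWeights(D * 0, mi$cat), "zero")
})

test_that("GIMME inputs reuse the INIT construction with threshold 1", {
  mi <- mem_instance()
  D <- thresholdDistances(mi$m, mi$cl, mi$ts)
  g <- gimmeInputs(D, mi$cat, protected = "RC")
  expect_equal(g$weights, initWeights(D, mi$cat, protected = "RC"))
  expect_equal(g$threshold, 1)
})

test_that("MBA bands split reactions into disjoint high and medium sets", {
  mi <- mem_instance()
  sets <- mbaSets(mi$m, mi$cl, mi$ts, mi$cat, band = 0.10)
  # e1 in s1: 100 > 1.1 * 10^1 -> RA high
  expect_true("RA" %in% sets$high$s1)
  # e2 in s1 sits exactly at its cutoff (10 within [9, 11]) -> RB medium
  expect_true("RB" %in% sets$medium$s1)
  expect_false("RB" %in% sets$high$s1)
  # disjointness per context
  for (ctx in names(sets$high))
    expect_length(intersect(sets$high[[ctx]], sets$medium[[ctx]]), 0)
  # a reaction with one high and one medium enzyme resolves to high
  m2 <- mi$m
  m2["e3", "s1"] <- 100   # e3 high in s1 while e2 is medium; both drive RB
  sets2 <- mbaSets(m2, mi$cl, mi$ts, mi$cat, band = 0.10)
  expect_true("RB" %in% sets2$high$s1)
  expect_false("RB" %in% sets2$medium$s1)
  # protected reactions are forced into high
  sets3 <- mbaSets(mi$m, mi$cl, mi$ts, mi$cat, protected = "RD")
  expect_true(all(vapply(sets3$high, function(s) "RD" %in% s, logical(1))))
  expect_error(mbaSets(mi$m, mi$cl, mi$ts, mi$cat, band = 1), "below 1")
})

test_that("iMAT partition tiles the catalog with the gene-free set", {
  mi <- mem_instance()
  core <- standepCore(mi$m, mi$cl, mi$ts, mi$cat, protected = character())
  im <- imatSets(core, mi$cat)
  for (ctx in names(im$core)) {
    expect_length(intersect(im$core[[ctx]], im$noncore[[ctx]]), 0)
    expect_false("RD" %in% im$noncore[[ctx]])  # gene-free in neither set
    expect_false("RD" %in% im$core[[ctx]])
    expect_setequal(c(im$core[[ctx]], im$noncore[[ctx]],
                      geneFreeReactions(mi$cat)),
                    reactionIds(mi$cat))
  }
})

test_that("the assembled bundle is internally consistent", {
  fx <- generateFixture(fixtureSpec(seed = 21))
  enz <- computeEnzymeExpression(fx$expression, fx$catalog)
  cl <- clusterEnzymes(enz, nClusters = 4)
  th <- suppressWarnings(standepThresholds(cl, enz))
  protected <- reactionIds(fx$catalog)[1]
  bundle <- buildMEMInputs(enz, cl, th, fx$catalog, protected = protected)
  expect_s4_class(bundle, "MEMInputBundle")
  U <- bundle@ubiquity
  geneful <- setdiff(rownames(U), geneFreeReactions(fx$catalog))
  retained <- unique(unlist(lapply(reactionEnzymes(fx$catalog)[geneful],
                                   intersect, enzymeIds(enz))))
  withData <- names(Filter(function(e) length(intersect(e, enzymeIds(enz))) > 0,
                           reactionEnzymes(fx$catalog)[geneful]))
  expect_true(all(U[withData, ] >= 0 & U[withData, ] <= 1))
  expect_true(all(U[geneFreeReactions(fx$catalog), ] == -1))
  expect_true(all(U[protected, ] == 1))
  # fastCORE core matches the standep core and includes the protected set
  expect_true(all(vapply(bundle@fastcoreCore,
                         function(s) protected %in% s, logical(1))))
  # writing produces the documented artifacts
  dir <- withr::local_tempdir()
  writeMEMInputs(bundle, dir)
  expect_true(all(file.exists(file.path(dir,
    c("mem_inputs.json", "mcadre_ubiquity.tsv", "init_weights.tsv",
      "gimme_weights.tsv")))))
})
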