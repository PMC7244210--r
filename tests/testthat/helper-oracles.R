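# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops and first-principles formulas, sharing no code
# with the package internals they check.

# Sort-and-interpolate quantile (linear interpolation between order
# statistics, the convention of stats::quantile type 7, written out by hand).
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  if (n == 1) return(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_top_percentile <- function(x, topPct) {
  oracle_quantile(x, (100 - topPct) / 100)
}

# Cluster and dataset log10 statistics recomputed with loops from a plain
# matrix and an assignment vector.
oracle_cluster_stats <- function(mat, assignment) {
  pool <- c()
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat)))
    if (mat[i, j] > 0) pool <- c(pool, log10(mat[i, j]))
  ks <- sort(unique(assignment))
  mu <- sigma <- numeric(length(ks))
  for (idx in seq_along(ks)) {
    vals <- c()
    for (e in names(assignment)[assignment == ks[idx]])
      for (j in seq_len(ncol(mat)))
        if (mat[e, j] > 0) vals <- c(vals, log10(mat[e, j]))
    mu[idx] <- mean(vals)
    sigma[idx] <- if (length(vals) > 1) sd(vals) else 0
  }
  list(mu = mu, sigma = sigma, M = mean(pool), Delta = sd(pool), k = ks)
}

# Raw thresholds: f(sigma_c) + g(mu_c) evaluated term by term.
oracle_theta <- function(mu, sigma, M, Delta) {
  d <- sigma - Delta
  dm <- max(d)
  f <- if (dm == 0) rep(0, length(d)) else d / dm
  g <- -(mu - M)
  f + g
}

# Affine normalisation of theta onto [0, 100].
oracle_theta_norm <- function(theta) {
  rng <- max(theta) - min(theta)
  if (rng == 0) return(rep(100, length(theta)))
  (theta - min(theta)) * 100 / rng
}

# Per-cluster cutoffs: top-Theta percentile of the cluster's pooled positive
# log10 values; Theta = 100 resolves to the dataset mean.
oracle_cutoffs <- function(mat, assignment, thetaNorm, M) {
  ks <- sort(unique(assignment))
  out <- numeric(length(ks))
  for (idx in seq_along(ks)) {
    if (thetaNorm[idx] >= 100 - 1e-9) { out[idx] <- M; next }
    vals <- c()
    for (e in names(assignment)[assignment == ks[idx]])
      for (j in seq_len(ncol(mat)))
        if (mat[e, j] > 0) vals <- c(vals, log10(mat[e, j]))
    out[idx] <- oracle_top_percentile(vals, thetaNorm[idx])
  }
  out
}

# Elementwise distances with an explicit zero floor.
oracle_distances <- function(mat, assignment, cutoffs, ks) {
  floorVal <- log10(min(mat[mat > 0])) - 1
  D <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat))) {
    lv <- if (mat[i, j] > 0) log10(mat[i, j]) else floorVal
    D[i, j] <- lv - cutoffs[match(assignment[rownames(mat)[i]], ks)]
  }
  D
}

# Enzyme-level ubiquity from distances; min over the negative entries of the
# whole matrix.
oracle_ubiquity_enzyme <- function(D) {
  U <- D
  neg <- D[D < 0]
  mn <- if (length(neg)) min(neg) else NA
  for (i in seq_len(nrow(D))) for (j in seq_len(ncol(D)))
    U[i, j] <- if (D[i, j] >= 0) 1 else 1 - D[i, j] / mn
  U
}

# Exact upper-tail hypergeometric P(X >= x) by combinatorial enumeration.
oracle_hyper_upper <- function(x, K, N, n) {
  p <- 0
  for (k in x:min(K, n))
    p <- p + choose(K, k) * choose(N - K, n - k) / choose(N, n)
  p
}

# Gini coefficient via the mean-absolute-pairwise-difference definition,
# normalized by n/(n-1).
oracle_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  (s / (2 * n^2 * mean(x))) * n / (n - 1)
}

# Evaluate a GPR rule string directly as a boolean expression under a given
# gene truth assignment (independent of the DNF decomposition).
oracle_gpr_eval <- function(gpr, truth) {
  expr <- gpr
  for (g in names(truth))
    expr <- gsub(paste0("\\b", g, "\\b"),
                 if (truth[[g]]) "TRUE" else "FALSE", expr)
  expr <- gsub("\\band\\b", "&&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "||", expr, ignore.case = TRUE)
  eval(parse(text = expr))
}

# Evaluate a DNF clause list under a truth assignment.
dnf_eval <- function(clauses, truth) {
  any(vapply(clauses, function(cl) all(unlist(truth[cl])), logical(1)))
}
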