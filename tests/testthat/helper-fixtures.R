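# Fixtures and independent oracles shared across the test files.  All
# fixtures are generated in code under fixed seeds; nothing is read from
# disk.

# A random additive matrix from a random tree, with `m` pairs masked.
# Truth under the mask is retained by delete_random_entries.
rand_additive_masked <- function(n, m, seed) {
  tr <- random_tree(n, seed = seed)
  delete_random_entries(additive_matrix(tr), m, seed = seed + 1000L)
}

# Simulate one pair of sequences at Jukes-Cantor distance d, directly from
# the closed-form site-difference probability p = 3/4 (1 - exp(-4d/3)).
# Independent of the package's tree-based simulator.
jc_pair <- function(L, d, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  x <- sample(bases, L, replace = TRUE)
  p <- 3 / 4 * (1 - exp(-4 * d / 3))
  y <- x
  flip <- runif(L) < p
  y[flip] <- vapply(x[flip], function(b) sample(setdiff(bases, b), 1),
                    character(1))
  list(x = paste(x, collapse = ""), y = paste(y, collapse = ""))
}

# Brute-force bipartition enumeration: delete each edge in turn and flood
# fill the leaf set of one component over the remaining edges.  Shares no
# code with bipartitions()/rf_rate().
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  n <- length(labs)
  E <- tree$edge
  out <- character(0)
  for (e in seq_len(nrow(E))) {
    keep <- E[-e, , drop = FALSE]
    comp <- E[e, 2]
    repeat {
      hit <- keep[, 1] %in% comp | keep[, 2] %in% comp
      grown <- unique(c(comp, keep[hit, 1], keep[hit, 2]))
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    side <- sort(labs[comp[comp <= n]])
    if (length(side) < 2 || length(side) > n - 2) next
    other <- paste(sort(setdiff(labs, side)), collapse = ",")
    out <- c(out, min(paste(side, collapse = ","), other))
  }
  unique(out)
}

oracle_rf_rate <- function(t1, t2) {
  b1 <- oracle_splits(t1)
  b2 <- oracle_splits(t2)
  denom <- length(b1) + length(b2)
  if (denom == 0) return(0)
  (length(setdiff(b1, b2)) + length(setdiff(b2, b1))) / denom
}

# Plain-R reference for one SGD epoch over the observed lower-triangular
# entries in row-major order, mirroring the documented update rule.
ref_mf_epoch <- function(X, Y, R, obs, alpha, beta) {
  n <- nrow(R)
  E <- 0
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      if (!obs[i, j]) next
      e <- R[i, j] - sum(X[i, ] * Y[j, ])
      xi <- X[i, ]
      yj <- Y[j, ]
      X[i, ] <- xi + alpha * (2 * e * yj - beta * xi)
      Y[j, ] <- yj + alpha * (2 * e * xi - beta * yj)
      E <- E + e^2
    }
  }
  list(X = X, Y = Y, E = E)
}

# Disjoint gene removals for an indirect-missingness experiment: gene 1
# from the first n1 taxa, gene 2 from the next n2.
disjoint_removals <- function(labels, n1, n2) {
  stopifnot(n1 + n2 <= length(labels))
  c(stats::setNames(rep(list("gene1"), n1), labels[seq_len(n1)]),
    stats::setNames(rep(list("gene2"), n2), labels[n1 + seq_len(n2)]))
}
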