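test_that("neighbor joining recovers the quartet from an additive matrix", {
  labs <- c("A", "B", "C", "D")
  v <- matrix(3, 4, 4, dimnames = list(labs, labs))
  v[1, 2] <- v[2, 1] <- 2
  v[3, 4] <- v[4, 3] <- 2
  diag(v) <- 0
  tree <- nj_tree(masked_dist_matrix(v))
  expect_identical(bipartitions(tree), "A,B")  # split AB|CD
})

test_that("three-taxon edge lengths follow the three-point formulas", {
  labs <- c("A", "B", "C")
  v <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3, dimnames = list(labs, labs))
  tree <- nj_tree(masked_dist_matrix(v))
  lens <- setNames(tree$edge.length,
                   tree$tip.label[tree$edge[, 2]])
  expect_equal(lens[["A"]], 1)
  expect_equal(lens[["B"]], 1)
  expect_equal(lens[["C"]], 3)
})

test_that("two taxa give a single edge of the pairwise distance", {
  v <- matrix(c(0, 1.7, 1.7, 0), 2, 2)
  tree <- nj_tree(masked_dist_matrix(v, labels = c("A", "B")))
  expect_identical(sort(tree$tip.label), c("A", "B"))
  expect_equal(sum(tree$edge.length), 1.7)
})

test_that("incomplete matrices are rejected by the tree builder", {
  m <- rand_additive_masked(6, 2, seed = 1)
  expect_error(nj_tree(m), "impute")
})

test_that("bipartition sets have the expected size and content", {
  quartet <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_identical(bipartitions(quartet), "A,B")
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1);")
  expect_identical(bipartitions(star), character(0))
  for (n in c(5, 8, 12)) {
    cat_txt <- paste0(paste(rep("(", n - 1), collapse = ""), "L1:1,",
                      paste(sprintf("L%d:1):1,", 2:(n - 1)), collapse = ""),
                      sprintf("L%d:1);", n))
    caterpillar <- read_newick(text = cat_txt)
    expect_length(bipartitions(caterpillar), n - 3)
  }
})

test_that("RF rate matches hand-enumerated splits", {
  t1 <- read_newick(text = "((A,B),C,(D,E));")
  t2 <- read_newick(text = "((A,C),B,(D,E));")
  expect_equal(rf_rate(t1, t1), 0)
  expect_equal(rf_rate(t1, t2), 0.5)  # shares DE|ABC only: 2 of 4 splits differ
  # maximally different 6-leaf caterpillars share no splits
  c1 <- read_newick(text = "(((((A,B),C),D),E),F);")
  c2 <- read_newick(text = "(((((A,C),E),B),D),F);")
  expect_equal(rf_rate(c1, c2), 1)
  expect_error(rf_rate(t1, c1), "leaf label set")
})

test_that("RF rate equals the brute-force oracle and the n<=3 convention", {
  skip_if_not_installed("phangorn")
  trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = paste0("x", 1:5))
  for (i in seq_along(trees)) {
    for (j in seq.int(i, length(trees))) {
      r <- rf_rate(trees[[i]], trees[[j]])
      expect_equal(r, oracle_rf_rate(trees[[i]], trees[[j]]))
      expect_equal(r, rf_rate(trees[[j]], trees[[i]]))  # symmetric
      expect_true(r >= 0 && r <= 1)
    }
  }
  tri <- read_newick(text = "(A:1,B:1,C:1);")
  expect_equal(rf_rate(tri, tri), 0)
})

test_that("RF rate agrees with an established implementation", {
  skip_if_not_installed("phangorn")
  for (s in 1:10) {
    t1 <- random_tree(12, seed = s)
    t2 <- random_tree(12, seed = 100 + s)
    expect_equal(rf_rate(t1, t2),
                 as.numeric(phangorn::RF.dist(t1, t2)) / (2 * (12 - 3)))
  }
})

test_that("newick round-trips preserve topology and branch lengths", {
  t0 <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  path <- withr::local_tempfile()
  write_newick(t0, path)
  expect_equal(rf_rate(read_newick(path), t0), 0)

  t2 <- read_newick(text = "(A:1,B:2);")
  expect_equal(sum(t2$edge.length), 3)

  for (s in 1:5) {
    tr <- random_tree(10, seed = s)
    write_newick(tr, path)
    back <- read_newick(path)
    expect_equal(rf_rate(back, tr), 0)
    d1 <- additive_matrix(tr)
    d2 <- additive_matrix(back)
    expect_equal(d2$values[d1$labels, d1$labels], d1$values,
                 tolerance = 1e-9)
    # writing again is idempotent
    path2 <- withr::local_tempfile()
    write_newick(back, path2)
    expect_identical(readLines(path2), readLines(path))
  }
  expect_error(read_newick(text = "((A,B);"))
})

test_that("additive matrices are path-length sums", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):0);")
  m <- additive_matrix(tr)
  expect_equal(m$values["A", "B"], 2)
  expect_equal(m$values["A", "C"], 3)
  expect_true(is_complete(m))

  t2 <- read_newick(text = "(A:1,B:2);")
  m2 <- additive_matrix(t2)
  expect_identical(dim(m2$values), c(2L, 2L))
  expect_equal(m2$values["A", "B"], 3)
})

test_that("NJ recovers the topology of random additive matrices", {
  for (s in 1:10) {
    tr <- random_tree(5 + s, seed = 200 + s)
    expect_equal(rf_rate(nj_tree(additive_matrix(tr)), tr), 0)
  }
})
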