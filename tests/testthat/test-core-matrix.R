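test_that("matrix I/O round-trips labels, values and mask exactly", {
  m <- rand_additive_masked(10, 5, seed = 3)
  m$values[m$mask] <- NA_real_  # file carries no values under the mask
  path <- withr::local_tempfile()
  write_dist_matrix(m, path)
  m2 <- read_dist_matrix(path)
  expect_identical(m2$labels, m$labels)
  expect_identical(unname(m2$mask), unname(m$mask))
  expect_equal(unname(m2$values[!m2$mask]), unname(m$values[!m$mask]),
               tolerance = 1e-12)
  # bit-exact, in fact: 17 significant digits survive the round trip
  expect_identical(unname(m2$values[!m2$mask]), unname(m$values[!m$mask]))
})

test_that("missing markers are emitted exactly twice per masked pair", {
  m <- rand_additive_masked(10, 5, seed = 7)
  path <- withr::local_tempfile()
  write_dist_matrix(m, path)
  tokens <- unlist(strsplit(readLines(path), "\\s+"))
  expect_identical(sum(tokens == "NA"), 10L)

  complete <- additive_matrix(random_tree(6, seed = 2))
  write_dist_matrix(complete, path)
  tokens <- unlist(strsplit(readLines(path), "\\s+"))
  expect_identical(sum(tokens == "NA"), 0L)
})

test_that("a complete n-taxon matrix holds n(n-1)/2 deletable pairs", {
  m <- additive_matrix(random_tree(24, seed = 9))
  expect_identical(missing_count(m), 0L)
  all_gone <- delete_random_entries(m, 276, seed = 1)
  expect_identical(missing_count(all_gone), 276L)
  expect_error(delete_random_entries(m, 277, seed = 1), "only 276 observed")
})

test_that("constructor rejects every invariant violation", {
  good <- additive_matrix(random_tree(6, seed = 4))
  expect_s3_class(masked_dist_matrix(good$values, good$mask, good$labels),
                  "masked_dist")

  for (corrupt in list(
    function(m) { m$values[2, 3] <- m$values[2, 3] + 1; m },   # asymmetric
    function(m) { m$values[2, 3] <- m$values[3, 2] <- -1; m }, # negative
    function(m) { m$values[1, 1] <- 0.5; m },                  # nonzero diag
    function(m) { m$mask[1, 1] <- TRUE; m },                   # masked diag
    function(m) { m$mask[2, 3] <- TRUE; m },                   # asym mask
    function(m) { m$values[2, 3] <- m$values[3, 2] <- Inf; m },
    function(m) { m$labels[2] <- m$labels[1]; m },             # duplicate
    function(m) { m$labels[2] <- "a b"; m }                    # whitespace
  )) {
    bad <- corrupt(good)
    expect_error(masked_dist_matrix(bad$values, bad$mask, bad$labels))
  }
})

test_that("reader rejects malformed files and repairs only when asked", {
  path <- withr::local_tempfile()

  writeLines(c("3", "a 0 1 2", "b 1 0", "c 2 1 0"), path)
  expect_error(read_dist_matrix(path), "non-square")

  writeLines(c("2", "a 0 1", "a 1 0"), path)
  expect_error(read_dist_matrix(path), "duplicate")

  writeLines(c("2", "a 0 -1", "b -1 0"), path)
  expect_error(read_dist_matrix(path), "negative")

  writeLines(c("2", "a NA 1", "b 1 0"), path)
  expect_error(read_dist_matrix(path), "diagonal")

  # value asymmetry
  writeLines(c("2", "a 0 1", "b 2 0"), path)
  expect_error(read_dist_matrix(path), "asymmetric")
  fixed <- read_dist_matrix(path, symmetrize = TRUE)
  expect_equal(fixed$values[1, 2], 1.5)

  # half-missing pair
  writeLines(c("2", "a 0 NA", "b 1 0"), path)
  expect_error(read_dist_matrix(path), "asymmetric")
  fixed <- read_dist_matrix(path, symmetrize = TRUE)
  expect_identical(missing_count(fixed), 1L)
})

test_that("single masked pair reads back as one missing pair", {
  path <- withr::local_tempfile()
  writeLines(c("3", "a 0 NA 2", "b NA 0 3", "c 2 3 0"), path)
  m <- read_dist_matrix(path)
  expect_identical(missing_count(m), 1L)
  expect_true(m$mask[1, 2] && m$mask[2, 1])
})

test_that("missing_count is an integer half of the masked cells", {
  for (seed in 1:5) {
    m <- rand_additive_masked(8, seed %% 4L + 1L, seed)
    expect_identical(missing_count(m), seed %% 4L + 1L)
    expect_identical(sum(m$mask) %% 2L, 0L)
  }
})

test_that("mean fill completes a matrix without touching observed cells", {
  m <- rand_additive_masked(9, 6, seed = 11)
  filled <- mean_fill_impute(m)
  expect_true(is_complete(filled))
  expect_identical(filled$values[!m$mask], m$values[!m$mask])
  obs_mean <- mean(m$values[!m$mask & upper.tri(m$mask)])
  expect_true(all(filled$values[m$mask] == obs_mean))
})
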