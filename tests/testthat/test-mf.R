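test_that("prediction is the K-term inner product", {
  fp <- list(X = matrix(0.5, 1, 1), Y = matrix(0.5, 1, 1))
  expect_equal(mf_predict(fp, 1, 1), 0.25)

  set.seed(8)
  n <- 7
  fp <- list(X = matrix(rnorm(n * n), n, n), Y = matrix(rnorm(n * n), n, n))
  for (i in 1:n) {
    for (j in 1:n) {
      brute <- 0
      for (k in 1:n) brute <- brute + fp$X[i, k] * fp$Y[j, k]
      expect_equal(mf_predict(fp, i, j), brute)
    }
  }
  expect_equal(mf_predict(list(X = matrix(0, 3, 3), Y = matrix(1, 3, 3)), 2, 3), 0)
})

test_that("the per-entry update matches its printed closed form", {
  up <- mf_update_entry(0.5, 0.5, r = 1, alpha = 0.002, beta = 0.02)
  expect_equal(up$e, 0.75)
  expect_equal(up$x, 0.50148)
  expect_equal(up$y, 0.50148)
  # zero residual, zero regularization: nothing moves
  up0 <- mf_update_entry(c(1, 2), c(0.5, 0.25), r = 1, alpha = 0.01, beta = 0)
  expect_equal(up0$e, 0)
  expect_identical(up0$x, c(1, 2))
  expect_identical(up0$y, c(0.5, 0.25))
})

test_that("update direction equals the gradient of the per-entry objective", {
  # objective: (r - x.y)^2 + (beta/2)(||x||^2 + ||y||^2); the update step is
  # -alpha times its gradient.  Central finite differences, 100 triples.
  obj <- function(x, y, r, beta) (r - sum(x * y))^2 + beta / 2 * (sum(x^2) + sum(y^2))
  set.seed(5)
  h <- 1e-6
  worst <- 0
  for (rep in 1:100) {
    K <- sample(1:6, 1)
    x <- runif(K, -1, 1); y <- runif(K, -1, 1); r <- runif(1, -2, 2)
    beta <- sample(c(0, 0.02, 0.5), 1)
    up <- mf_update_entry(x, y, r, alpha = 1, beta = beta)
    step <- c(up$x - x, up$y - y)   # = -gradient at alpha = 1
    num <- numeric(2 * K)
    for (k in seq_len(K)) {
      ek <- replace(numeric(K), k, h)
      num[k] <- (obj(x + ek, y, r, beta) - obj(x - ek, y, r, beta)) / (2 * h)
      num[K + k] <- (obj(x, y + ek, r, beta) - obj(x, y - ek, r, beta)) / (2 * h)
    }
    worst <- max(worst, max(abs(step + num)) / max(1, max(abs(num))))
  }
  expect_lt(worst, 1e-6)
})

test_that("one training epoch agrees with the plain-R reference", {
  m <- rand_additive_masked(7, 4, seed = 17)
  n <- n_taxa(m)
  cfg <- mf_config(max_iter = 1, seed = 23)
  fit <- mf_train(m, cfg)
  set.seed(23)
  X0 <- matrix(runif(n * n), n, n)
  Y0 <- matrix(runif(n * n), n, n)
  R <- m$values; R[m$mask] <- 0
  ref <- ref_mf_epoch(X0, Y0, R, !m$mask, cfg$alpha, cfg$beta)
  expect_equal(fit$X, ref$X, tolerance = 1e-14)
  expect_equal(fit$Y, ref$Y, tolerance = 1e-14)
  expect_equal(fit$error_trace, ref$E, tolerance = 1e-14)
})

test_that("a rank-1 problem is fit to the convergence threshold", {
  v <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  m <- masked_dist_matrix(v, labels = c("a", "b"))
  fp <- mf_train(m, mf_config(beta = 0, seed = 1))
  expect_lt(fp$error_trace[fp$iterations], 1e-6)
  expect_true(all(diff(fp$error_trace) <= 0))
  expect_lt(abs(mf_predict(fp, 2, 1) - 0.6), 0.005)
})

test_that("training is deterministic given seed and config", {
  m <- rand_additive_masked(8, 6, seed = 19)
  cfg <- mf_config(max_iter = 200, seed = 99)
  a <- mf_train(m, cfg)
  b <- mf_train(m, cfg)
  expect_identical(a$error_trace, b$error_trace)
  expect_identical(a$X, b$X)
  expect_false(identical(mf_train(m, mf_config(max_iter = 200, seed = 100))$X,
                         a$X))
})

test_that("error trace does not increase on unit-scaled inputs", {
  set.seed(77)
  v <- matrix(0, 10, 10); v[upper.tri(v)] <- runif(45); v <- v + t(v)
  m <- delete_random_entries(masked_dist_matrix(v, labels = paste0("s", 1:10)),
                             5, seed = 7)
  fp <- mf_train(m, mf_config(max_iter = 2000, seed = 3))
  expect_lte(fp$error_trace[fp$iterations], fp$error_trace[1])
})

test_that("training on an all-missing matrix is an error", {
  v <- matrix(c(0, NA, NA, 0), 2, 2)
  m <- masked_dist_matrix(v, labels = c("a", "b"))
  expect_error(mf_train(m), "missing")
})

test_that("imputation fills only the masked cells and keeps contracts", {
  m <- rand_additive_masked(9, 7, seed = 29)
  out <- mf_impute(m, mf_config(max_iter = 500, seed = 5))
  expect_true(is_complete(out))
  expect_identical(out$values[!m$mask], m$values[!m$mask])  # bit-exact
  expect_identical(unname(out$values), unname(t(out$values)))
  expect_true(all(out$values >= 0))
  expect_true(all(diag(out$values) == 0))
  # complete input comes back untouched, no training
  complete <- additive_matrix(random_tree(6, seed = 30))
  expect_identical(mf_impute(complete), complete)
})
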