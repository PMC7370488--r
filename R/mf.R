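#' Matrix factorization imputation configuration
#'
#' Hyper-parameters for [mf_train()]/[mf_impute()].  Defaults follow the
#' values used throughout the package's benchmarks: learning rate
#' `alpha = 0.002`, regularization `beta = 0.02`, latent dimension
#' `K = N` (set when `K = NULL`), at most 10,000 epochs, and convergence
#' when the total squared error over observed entries drops below `1e-6`.
#'
#' @param K latent dimension; `NULL` means "number of taxa".
#' @param alpha SGD learning rate (> 0).
#' @param beta L2 regularization weight (>= 0).
#' @param max_iter maximum number of epochs (one epoch = one pass over the
#'   observed lower-triangular entries in fixed row-major order).
#' @param tol stop when the per-epoch total squared error falls below this.
#' @param seed integer seed for the uniform `[0, 1)` initialization of the
#'   factors.
#' @return a list of class `"mf_config"`.
#' @export
mf_config <- function(K = NULL, alpha = 0.002, beta = 0.02,
                      max_iter = 10000L, tol = 1e-6, seed = 1L) {
  stopifnot(alpha > 0, beta >= 0, is.null(K) || K >= 1,
            tol > 0, max_iter >= 1)
  structure(list(K = K, alpha = alpha, beta = beta,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = seed),
            class = "mf_config")
}

#' Predicted distance from a factor pair
#'
#' The rank-`K` reconstruction \eqn{\hat r_{ij} = \sum_k x_{ik} y_{jk}},
#' i.e. entry `(i, j)` of `X %*% t(Y)`.
#'
#' @param fp a factor pair as returned by [mf_train()] (list with `X`, `Y`).
#' @param i,j row and column indices.
#' @return the predicted real value (unclamped).
#' @export
mf_predict <- function(fp, i, j) {
  sum(fp$X[i, ] * fp$Y[j, ])
}

#' One SGD update for a single observed entry
#'
#' Reference implementation of the per-entry update used inside
#' [mf_train()], exposed for inspection and testing.  Given the current
#' latent rows `x` (for taxon `i`) and `y` (for taxon `j`) and the observed
#' distance `r`, the residual is computed once and both rows are updated
#' simultaneously from their pre-update values:
#' \deqn{e = r - x \cdot y, \quad
#'       x_k' = x_k + \alpha (2 e y_k - \beta x_k), \quad
#'       y_k' = y_k + \alpha (2 e x_k - \beta y_k).}
#' With `beta = 0` this is exact gradient descent on \eqn{(r - x\cdot y)^2};
#' in general it descends the per-entry objective
#' \eqn{(r - x\cdot y)^2 + (\beta/2)(\|x\|^2 + \|y\|^2)}.
#'
#' @param x,y numeric latent vectors of equal length `K`.
#' @param r observed distance.
#' @param alpha learning rate.
#' @param beta regularization weight.
#' @return list with updated `x`, `y` and the residual `e`.
#' @export
mf_update_entry <- function(x, y, r, alpha = 0.002, beta = 0.02) {
  e <- r - sum(x * y)
  x_new <- x + alpha * (2 * e * y - beta * x)
  y_new <- y + alpha * (2 * e * x - beta * y)
  list(x = x_new, y = y_new, e = e)
}

#' Train the matrix factorization on the observed entries
#'
#' Factors `X` and `Y` (both `N x K`) are initialized uniformly on
#' `[0, 1)` from `cfg$seed` and trained by stochastic gradient descent over
#' the observed lower-triangular entries (see [mf_update_entry()] for the
#' update rule).  Training stops when the per-epoch total squared error
#' drops below `cfg$tol` or after `cfg$max_iter` epochs; a total error
#' exceeding `1e12` (or going non-finite) aborts with a divergence error.
#'
#' @param m a `"masked_dist"` object with at least one observed
#'   off-diagonal pair.
#' @param cfg an [mf_config()].
#' @return list of class `"factor_pair"` with `X`, `Y`, the per-epoch
#'   `error_trace` and the number of `iterations` run.
#' @export
mf_train <- function(m, cfg = mf_config()) {
  validate_masked_dist(m)
  n <- n_taxa(m)
  K <- as.integer(cfg$K %||% n)
  obs <- !m$mask
  if (!any(obs & lower.tri(obs))) stop("all off-diagonal entries are missing")
  init <- with_seed(cfg$seed, {
    list(X = matrix(runif(n * K), n, K), Y = matrix(runif(n * K), n, K))
  })
  vals <- m$values
  vals[m$mask] <- 0  # never visited: only observed entries are trained on
  fit <- mf_train_cpp(init$X, init$Y, vals, obs, cfg$alpha, cfg$beta,
                      cfg$max_iter, cfg$tol)
  structure(list(X = fit$X, Y = fit$Y, error_trace = fit$error_trace,
                 iterations = length(fit$error_trace)),
            class = "factor_pair")
}

#' Impute missing distances by matrix factorization
#'
#' Trains the factorization on the observed entries and fills every missing
#' pair `(i, j)` with `max(0, mf_predict(fp, i, j))` (taking `i > j` and
#' mirroring, so the result is exactly symmetric).  Observed entries are
#' copied verbatim; the diagonal stays 0.  A complete input is returned
#' unchanged without training.
#'
#' @inheritParams mf_train
#' @return a complete `"masked_dist"` (empty mask) with attributes
#'   `iterations`, `final_error` and `error_trace` describing the fit.
#' @export
mf_impute <- function(m, cfg = mf_config()) {
  validate_masked_dist(m)
  if (is_complete(m)) return(m)
  fp <- mf_train(m, cfg)
  rhat <- fp$X %*% t(fp$Y)
  v <- m$values
  idx <- which(m$mask & lower.tri(m$mask), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    v[i, j] <- v[j, i] <- max(0, rhat[i, j])
  }
  diag(v) <- 0
  out <- masked_dist_matrix(v, matrix(FALSE, nrow(v), ncol(v)), m$labels)
  attr(out, "iterations") <- fp$iterations
  attr(out, "final_error") <- fp$error_trace[fp$iterations]
  attr(out, "error_trace") <- fp$error_trace
  out
}
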