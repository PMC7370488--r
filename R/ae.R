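#' Autoencoder imputation configuration
#'
#' Hyper-parameters for [ae_impute()].  The network has three hidden ReLU
#' layers (default widths `N`, `ceiling(N/2)`, `N`, set when
#' `hidden_sizes = NULL`) and a sigmoid output layer; dropout (rate 0.75)
#' is applied to the hidden activations during training only.  After each
#' training iteration the network's deterministic predictions are blended
#' into the missing cells with weight `w`:
#' \eqn{x' = (1 - w) x + w p}.  Training stops when the masked
#' reconstruction loss drops below `tol` or after `max_iter` iterations.
#'
#' @param hidden_sizes integer vector of three hidden-layer widths, or
#'   `NULL` for the `N`-dependent default.
#' @param dropout dropout rate in `[0, 1)` applied to hidden activations
#'   during training.
#' @param w blend weight in `(0, 1]` for updating missing cells.
#' @param max_iter maximum number of training/blend iterations (one
#'   iteration = one full-batch gradient step on the `N` matrix rows).
#' @param tol stop when the masked reconstruction loss (sum of squared
#'   errors over observed cells of the scaled matrix) falls below this.
#' @param seed integer seed driving weight initialization, the random fill
#'   of missing cells, and the dropout masks.
#' @param learning_rate step size of the adaptive-moment (Adam) optimizer.
#' @return a list of class `"ae_config"`.
#' @export
ae_config <- function(hidden_sizes = NULL, dropout = 0.75, w = 0.5,
                      max_iter = 10000L, tol = 1e-6, seed = 1L,
                      learning_rate = 1e-3) {
  stopifnot(dropout >= 0, dropout < 1, w > 0, w <= 1,
            is.null(hidden_sizes) ||
              (length(hidden_sizes) == 3L && all(hidden_sizes >= 1)),
            max_iter >= 1, tol > 0, learning_rate > 0)
  structure(list(hidden_sizes = hidden_sizes, dropout = dropout, w = w,
                 max_iter = as.integer(max_iter), tol = tol, seed = seed,
                 learning_rate = learning_rate),
            class = "ae_config")
}

#' Scale a distance matrix into the unit interval
#'
#' The sigmoid output layer of the autoencoder produces values in
#' `(0, 1)`, so distances are divided by `scale = 1.05 * max(observed)`
#' before training; observed entries then lie in `[0, 1/1.05]`.
#' Multiplying by `scale` inverts the transform exactly on observed cells.
#' If every observed entry is zero the scale is 1 (with a warning) and the
#' values pass through unchanged.
#'
#' @param m a `"masked_dist"` object with at least one observed entry.
#' @return list with `values` (scaled matrix, `NA` under the mask) and
#'   `scale`.
#' @export
scale_matrix <- function(m) {
  obs <- !m$mask
  mx <- max(m$values[obs])
  if (mx <= 0) {
    warning("all observed entries are zero; using unit scale")
    s <- 1
  } else {
    s <- 1.05 * mx
  }
  v <- m$values / s
  v[m$mask] <- NA_real_
  list(values = v, scale = s)
}

#' Masked reconstruction loss
#'
#' The reconstruction error of the autoencoder: the sum of squared
#' differences between `R` and `R_prime` over the observed (non-missing)
#' cells only, \eqn{L(R, R') = \sum_{i \in NM} |R_i - R'_i|^2}.  Cells
#' under the mask contribute nothing.  Diagonal zeros are observed cells
#' and participate.
#'
#' @param R,R_prime numeric matrices of identical shape.
#' @param obs logical matrix, `TRUE` on observed cells.
#' @return the scalar loss.
#' @export
masked_mse <- function(R, R_prime, obs) {
  stopifnot(identical(dim(R), dim(R_prime)), identical(dim(R), dim(obs)))
  if (!any(obs)) stop("no observed cells")
  sum((R[obs] - R_prime[obs])^2)
}

#' Blend a prediction into a current value
#'
#' The convex-combination update applied to missing cells after each
#' training iteration: \eqn{x' = (1 - w) x + w p}.
#'
#' @param x current value(s).
#' @param p predicted value(s).
#' @param w blend weight in `(0, 1]`; `w = 1` replaces `x` by `p`.
#' @return the blended value(s).
#' @export
blend_update <- function(x, p, w) {
  stopifnot(w > 0, w <= 1)
  (1 - w) * x + w * p
}

# ---- internal network machinery ------------------------------------------

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

# Glorot-uniform initialization for layer dims c(N, h1, h2, h3, N).
ae_init <- function(dims) {
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(runif(dims[l] * dims[l + 1L], -lim, lim),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# Deterministic forward pass (no dropout): 3 hidden ReLU layers + sigmoid
# output.  X has one sample (matrix row) per row.
ae_forward <- function(X, net) {
  A <- X
  L <- length(net$W)
  for (l in seq_len(L - 1L)) {
    A <- relu(sweep(A %*% net$W[[l]], 2, net$b[[l]], "+"))
  }
  sigmoid(sweep(A %*% net$W[[L]], 2, net$b[[L]], "+"))
}

# One full-batch gradient step with inverted dropout on the hidden
# activations; loss = sum over observed cells of (T - O)^2.  Returns the
# gradients of all weights and biases.
ae_gradients <- function(X, Tmat, obs, net, dropout) {
  L <- length(net$W)
  keep <- 1 - dropout
  Z <- vector("list", L); A <- vector("list", L); D <- vector("list", L)
  Dm <- vector("list", L - 1L)
  Ain <- X
  for (l in seq_len(L - 1L)) {
    Z[[l]] <- sweep(Ain %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l]] <- relu(Z[[l]])
    Dm[[l]] <- matrix(runif(length(Z[[l]])) < keep, nrow(Z[[l]]), ncol(Z[[l]]))
    D[[l]] <- A[[l]] * Dm[[l]] / keep
    Ain <- D[[l]]
  }
  Z[[L]] <- sweep(Ain %*% net$W[[L]], 2, net$b[[L]], "+")
  O <- sigmoid(Z[[L]])

  gW <- vector("list", L); gb <- vector("list", L)
  dZ <- -2 * (Tmat - O) * obs * O * (1 - O)
  for (l in rev(seq_len(L))) {
    Aprev <- if (l == 1L) X else D[[l - 1L]]
    gW[[l]] <- crossprod(Aprev, dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dD <- dZ %*% t(net$W[[l]])
      dA <- dD * Dm[[l - 1L]] / keep
      dZ <- dA * (Z[[l - 1L]] > 0)
    }
  }
  list(gW = gW, gb = gb)
}

adam_init <- function(net) {
  zeros <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
       mb = lapply(net$b, zeros), vb = lapply(net$b, zeros), t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

#' Impute missing distances with an undercomplete autoencoder
#'
#' The scaled matrix rows are the training samples: the network (input
#' width `N`, three hidden ReLU layers, sigmoid output of width `N`) is
#' trained to reconstruct each row, with the loss summed over observed
#' cells only ([masked_mse()]).  The procedure is:
#'
#' 1. scale the matrix into the unit interval ([scale_matrix()]);
#' 2. fill missing cells with seeded uniform draws from
#'    `[0, max scaled observed)`;
#' 3. iterate: one full-batch Adam step with dropout active, then compute
#'    the deterministic (no-dropout) reconstruction, record its masked
#'    loss, and blend it into the missing cells ([blend_update()]);
#' 4. stop when the recorded loss falls below `cfg$tol` or after
#'    `cfg$max_iter` iterations;
#' 5. unscale; restore observed entries verbatim; symmetrize imputed cells
#'    by averaging `(i, j)` and `(j, i)`; zero the diagonal.
#'
#' All randomness (weight initialization, random fill, dropout masks)
#' derives from `cfg$seed`, so identical inputs and configs give bit
#' identical outputs.  A complete input is returned unchanged without
#' training.
#'
#' @param m a `"masked_dist"` object with at least 2 taxa and at least one
#'   observed off-diagonal pair.
#' @param cfg an [ae_config()].
#' @return a complete `"masked_dist"` (empty mask) with attributes
#'   `iterations`, `final_loss` and `loss_trace`.
#' @export
ae_impute <- function(m, cfg = ae_config()) {
  validate_masked_dist(m)
  if (is_complete(m)) return(m)
  n <- n_taxa(m)
  if (n < 2L) stop("at least 2 taxa required")
  obs <- !m$mask
  if (!any(obs & lower.tri(obs))) stop("all off-diagonal entries are missing")
  hs <- cfg$hidden_sizes %||% c(n, ceiling(n / 2), n)
  sc <- scale_matrix(m)
  Tmat <- sc$values
  Tmat[m$mask] <- 0  # targets under the mask are never read by the loss
  max_obs <- max(Tmat[obs])

  res <- with_seed(cfg$seed, {
    net <- ae_init(c(n, hs, n))
    state <- adam_init(net)
    Xcur <- Tmat
    Xcur[m$mask] <- runif(sum(m$mask), 0, max_obs)
    init_fill <- Xcur[m$mask]
    trace <- numeric(cfg$max_iter)
    iters <- 0L
    for (it in seq_len(cfg$max_iter)) {
      grads <- ae_gradients(Xcur, Tmat, obs, net, cfg$dropout)
      upd <- adam_step(net, grads, state, cfg$learning_rate)
      net <- upd$net; state <- upd$state
      O <- ae_forward(Xcur, net)
      loss <- masked_mse(Tmat, O, obs)
      if (!is.finite(loss)) {
        stop(sprintf("autoencoder loss diverged at iteration %d (seed %s, lr %g)",
                     it, format(cfg$seed), cfg$learning_rate))
      }
      iters <- it
      trace[it] <- loss
      Xcur[m$mask] <- blend_update(Xcur[m$mask], O[m$mask], cfg$w)
      if (loss < cfg$tol) break
    }
    list(Xcur = Xcur, trace = trace[seq_len(iters)], iterations = iters,
         init_fill = init_fill)
  })

  v <- res$Xcur * sc$scale
  v[obs] <- m$values[obs]            # observed cells restored verbatim
  sym <- (v + t(v)) / 2
  v[m$mask] <- pmax(0, sym[m$mask])  # imputed cells symmetrized
  diag(v) <- 0
  out <- masked_dist_matrix(v, matrix(FALSE, n, n), m$labels)
  attr(out, "iterations") <- res$iterations
  attr(out, "final_loss") <- res$trace[res$iterations]
  attr(out, "loss_trace") <- res$trace
  # the unscaled initial random guesses for the masked cells, in mask order,
  # kept so benchmarks can compare the trained fill against its start
  attr(out, "initial_fill") <- res$init_fill * sc$scale
  out
}
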