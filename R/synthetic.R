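#' Random binary tree
#'
#' Generates an unrooted binary topology by sequential random leaf
#' attachment: starting from the two-leaf tree, each new leaf is attached
#' to an edge chosen uniformly at random.  Branch lengths are drawn
#' i.i.d. uniform on `bl_range`.  Fully determined by `seed`.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param bl_range branch-length range `c(lo, hi)`, `lo > 0`.
#' @param seed integer seed.
#' @param labels leaf labels; default `t1..tn`.
#' @return an unrooted `phylo` tree with `2 * n_taxa - 3` edges.
#' @export
random_tree <- function(n_taxa, bl_range = c(0.05, 0.5), seed = 1L,
                        labels = paste0("t", seq_len(n_taxa))) {
  if (n_taxa < 2L) stop("at least 2 taxa required")
  stopifnot(length(bl_range) == 2L, bl_range[1] > 0,
            bl_range[2] >= bl_range[1], length(labels) == n_taxa)
  with_seed(seed, {
    # Node ids: 1..n tips, n+1.. internal.  Grow the edge list.
    edges <- matrix(c(1L, 2L), 1, 2)
    nxt <- n_taxa + 1L
    for (k in seq_len(n_taxa)) {
      if (k <= 2L) next
      e <- sample.int(nrow(edges), 1L)
      u <- edges[e, 1]; v <- edges[e, 2]
      edges[e, ] <- c(u, nxt)
      edges <- rbind(edges, c(nxt, v), c(nxt, k))
      nxt <- nxt + 1L
    }
    lens <- runif(nrow(edges), bl_range[1], bl_range[2])
    if (n_taxa == 2L) {
      txt <- sprintf("(%s:%.17g,%s:%.17g);", labels[1], lens[1] / 2,
                     labels[2], lens[1] / 2)
      return(ape::read.tree(text = txt))
    }
    # Adjacency with edge indices, then newick by DFS from an internal node.
    n_nodes <- nxt - 1L
    adj <- vector("list", n_nodes)
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      adj[[u]] <- rbind(adj[[u]], c(v, e))
      adj[[v]] <- rbind(adj[[v]], c(u, e))
    }
    build <- function(node, parent) {
      nb <- adj[[node]]
      nb <- nb[nb[, 1] != parent, , drop = FALSE]
      if (nrow(nb) == 0L) return(labels[node])
      parts <- vapply(seq_len(nrow(nb)), function(r) {
        paste0(build(nb[r, 1], node), ":",
               sprintf("%.17g", lens[nb[r, 2]]))
      }, character(1))
      paste0("(", paste(parts, collapse = ","), ")")
    }
    root <- n_taxa + 1L
    ape::read.tree(text = paste0(build(root, 0L), ";"))
  })
}

#' Additive matrix with multiplicative noise
#'
#' Perturbs each pairwise path length of `tree` by an independent factor
#' `1 + eps`, `eps ~ Normal(0, sigma^2)`, redrawn until the factor is
#' positive so entries stay positive.  `sigma = 0` returns the exact
#' additive matrix.  Used to emulate the estimation noise of real
#' distance matrices without simulating sequences.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return a complete [masked_dist_matrix()].
#' @export
perturbed_matrix <- function(tree, sigma, seed = 1L) {
  if (sigma < 0) stop("`sigma` must be non-negative")
  m <- additive_matrix(tree)
  if (sigma == 0) return(m)
  v <- m$values
  n <- nrow(v)
  with_seed(seed, {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        repeat {
          f <- 1 + rnorm(1, 0, sigma)
          if (f > 0) break
        }
        v[i, j] <- v[j, i] <- v[i, j] * f
      }
    }
  })
  masked_dist_matrix(v, matrix(FALSE, n, n), m$labels)
}

# ---- HKY substitution model ----------------------------------------------

# Rate matrix of the HKY85 model, normalized to one expected substitution
# per unit branch length at stationarity.  kappa = 1 with uniform
# frequencies is Jukes-Cantor.
hky_rate_matrix <- function(kappa, freqs) {
  stopifnot(kappa > 0, length(freqs) == 4L, all(freqs > 0),
            abs(sum(freqs) - 1) < 1e-8)
  transit <- matrix(FALSE, 4, 4)
  transit[1, 3] <- transit[3, 1] <- TRUE  # A <-> G
  transit[2, 4] <- transit[4, 2] <- TRUE  # C <-> T
  Q <- matrix(rep(freqs, each = 4), 4, 4)
  Q[transit] <- Q[transit] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# Transition probability matrix P(t) = exp(Qt), computed exactly through
# the spectral decomposition of the reversible rate matrix.
hky_pmatrix <- function(t, kappa, freqs) {
  Q <- hky_rate_matrix(kappa, freqs)
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / sp) %*% es$vectors %*% diag(exp(t * es$values)) %*%
    t(es$vectors) %*% diag(sp)
  P <- pmax(P, 0)
  P / rowSums(P)
}

#' Simulate a two-gene alignment along a tree
#'
#' Evolves i.i.d. sites down `tree` under the HKY85 (or Jukes–Cantor)
#' continuous-time Markov model: the root state of each site is drawn from
#' the stationary frequencies and each branch applies the exact transition
#' matrix `exp(Q t)`.  The sites are organised as named contiguous gene
#' blocks (default two genes), emulating concatenated multi-gene data so
#' that [remove_gene_blocks()] can create indirect missingness.
#'
#' @param tree a `phylo` tree with branch lengths (substitutions/site).
#' @param gene_lengths named integer vector of per-gene site counts.
#' @param model `"hky"` or `"jc"` (`jc` forces `kappa = 1`, uniform
#'   frequencies).
#' @param kappa transition/transversion rate ratio.
#' @param freqs stationary base frequencies `(A, C, G, T)`, summing to 1.
#' @param seed integer seed.
#' @return list with `alignment` (an [alignment()]) and `partition` (a
#'   [gene_partition()]).
#' @export
simulate_alignment <- function(tree, gene_lengths = c(gene1 = 1000, gene2 = 1000),
                               model = c("hky", "jc"), kappa = 2,
                               freqs = rep(0.25, 4), seed = 1L) {
  model <- match.arg(model)
  if (model == "jc") {
    kappa <- 1
    freqs <- rep(0.25, 4)
  }
  if (is.null(names(gene_lengths)) || any(!nzchar(names(gene_lengths)))) {
    stop("`gene_lengths` must be named")
  }
  stopifnot(all(gene_lengths >= 1))
  L <- sum(gene_lengths)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n <- length(tr$tip.label)
  root <- tr$edge[1, 1]
  states <- matrix(0L, n + tr$Nnode, L)
  with_seed(seed, {
    states[root, ] <- sample.int(4L, L, replace = TRUE, prob = freqs)
    for (e in seq_len(nrow(tr$edge))) {
      P <- hky_pmatrix(tr$edge.length[e], kappa, freqs)
      ps <- states[tr$edge[e, 1], ]
      cs <- integer(L)
      for (s in 1:4) {
        idx <- which(ps == s)
        if (length(idx)) {
          cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
        }
      }
      states[tr$edge[e, 2], ] <- cs
    }
  })
  bases <- c("A", "C", "G", "T")
  seqs <- apply(states[seq_len(n), , drop = FALSE], 1,
                function(r) paste(bases[r], collapse = ""))
  ends <- cumsum(gene_lengths)
  starts <- ends - gene_lengths + 1L
  list(alignment = alignment(tr$tip.label, seqs),
       partition = gene_partition(names(gene_lengths), starts, ends))
}
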