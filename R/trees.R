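#' Neighbor-joining tree from a complete distance matrix
#'
#' Standard Saitou–Nei agglomeration (via ape's implementation of the
#' Q-criterion) on a complete [masked_dist_matrix()].  Negative branch
#' lengths produced by the algorithm are clamped to 0 and the result is
#' returned unrooted.  A matrix with missing entries is rejected — impute
#' first ([mf_impute()], [ae_impute()], [mean_fill_impute()]).
#'
#' @param m a complete `"masked_dist"` object (`N >= 2`).
#' @return an unrooted `phylo` tree on the matrix's taxa.
#' @export
nj_tree <- function(m) {
  validate_masked_dist(m)
  if (!is_complete(m)) {
    stop("matrix has missing entries; impute before building a tree")
  }
  n <- n_taxa(m)
  if (n < 2L) stop("at least 2 taxa required")
  if (n == 2L) {
    d <- m$values[1, 2]
    txt <- sprintf("(%s:%.17g,%s:%.17g);", m$labels[1], d / 2,
                   m$labels[2], d / 2)
    return(ape::read.tree(text = txt))
  }
  tree <- ape::nj(stats::as.dist(m$values))
  tree$edge.length <- pmax(tree$edge.length, 0)
  ape::unroot(tree)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves into two sets
#' (a bipartition).  Trivial splits (single leaf vs the rest) are
#' excluded.  Every split is returned in canonical form — the
#' lexicographically smaller of its two sides, as a comma-joined string of
#' sorted labels — so split sets of different trees on the same leaves are
#' directly comparable.  For a binary unrooted tree on `n` leaves there
#' are exactly `n - 3` non-trivial splits.
#'
#' @param tree a `phylo` tree.
#' @return character vector of canonical splits (possibly empty).
#' @export
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  if (anyDuplicated(labs)) stop("duplicate tip labels")
  n <- length(labs)
  if (n < 4L || tree$Nnode < 2L) return(character(0))
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (cl in pp) {
    sz <- length(cl)
    if (sz < 2L || sz > n - 2L) next  # trivial or whole-leaf set
    side1 <- paste(sort(labs[cl]), collapse = ",")
    side2 <- paste(sort(labs[-cl]), collapse = ",")
    out <- c(out, min(side1, side2))
  }
  unique(out)
}

#' Normalized Robinson–Foulds rate between two trees
#'
#' The RF distance is the number of bipartitions induced by one tree but
#' not the other, summed both ways (the symmetric difference of the two
#' split sets).  The rate divides by the maximum possible RF distance,
#' `|B1| + |B2|` — which equals `2(n - 3)` when both trees are binary — so
#' it lies in `[0, 1]`; identical split sets give 0.  When both trees have
#' no non-trivial splits (`n <= 3`) the rate is defined as 0.
#'
#' @param t1,t2 `phylo` trees on the same leaf label set.
#' @return the RF rate in `[0, 1]`.
#' @export
rf_rate <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    stop("trees must share an identical leaf label set")
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  denom <- length(b1) + length(b2)
  if (denom == 0L) return(0)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  rf / denom
}

#' Read / write newick trees
#'
#' Wrappers around ape's newick parser and writer.  Trees are unrooted on
#' read; a round trip preserves topology, labels and branch lengths well
#' within `1e-9`.
#'
#' @param path path to a newick file, or `NULL` when `text` is given.
#' @param text a newick string, used instead of `path` when non-`NULL`.
#' @return `read_newick()` returns an unrooted `phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(path)
  if (is.null(tree)) stop("malformed newick input")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (length(tree$tip.label) > 2L) tree <- ape::unroot(tree)
  tree
}

#' @param tree a `phylo` tree.
#' @rdname read_newick
#' @return `write_newick()` returns `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Additive (path-length) distance matrix of a tree
#'
#' The ground-truth matrix for synthetic benchmarks: entry `(i, j)` is the
#' sum of branch lengths on the path between leaves `i` and `j`.  The
#' result is complete, symmetric and zero on the diagonal; neighbor
#' joining provably recovers the tree topology from it.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return a complete [masked_dist_matrix()] in the tree's tip order.
#' @export
additive_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  D <- ape::cophenetic.phylo(tree)
  D <- D[tree$tip.label, tree$tip.label]
  masked_dist_matrix(D, matrix(FALSE, nrow(D), ncol(D)), tree$tip.label)
}
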