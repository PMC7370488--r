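#' Randomly delete entries of a distance matrix (direct missingness)
#'
#' Masks `m` additional unordered taxon pairs chosen uniformly without
#' replacement among the currently observed off-diagonal pairs.  Both
#' `(i, j)` and `(j, i)` are masked together; the diagonal is never
#' touched.  The deleted values are retained in the `values` slot under the
#' new mask so that imputation error can be measured against them — they
#' are never written to disk by [write_dist_matrix()].
#'
#' @param m a `"masked_dist"` object.
#' @param n_delete number of additional pairs to mask; must not exceed the
#'   number of observed off-diagonal pairs.
#' @param seed integer seed; the same seed always selects the same pairs.
#' @return a `"masked_dist"` with `missing_count` increased by `n_delete`.
#' @export
delete_random_entries <- function(m, n_delete, seed) {
  validate_masked_dist(m)
  if (n_delete < 0) stop("`n_delete` must be non-negative")
  obs <- which(!m$mask & upper.tri(m$mask))
  if (n_delete > length(obs)) {
    stop(sprintf("cannot delete %d pairs: only %d observed", n_delete,
                 length(obs)))
  }
  if (n_delete == 0) return(m)
  pick <- with_seed(seed, sample(obs, n_delete))
  mask <- m$mask
  mask[pick] <- TRUE
  mask <- mask | t(mask)
  out <- m
  out$mask <- mask
  dimnames(out$mask) <- dimnames(m$mask)
  validate_masked_dist(out)
}

#' Remove gene blocks from taxa (indirect missingness)
#'
#' Replaces the sites of the listed genes with `"?"` for the listed taxa,
#' leaving the alignment length unchanged.  When gene 1 is removed from a
#' set of `n1` taxa and gene 2 from a disjoint set of `n2` taxa in a
#' two-gene alignment, each cross pair shares no homologous sites, so the
#' downstream distance matrix acquires exactly `n1 * n2` missing entries.
#'
#' @param aln an [alignment()].
#' @param part a [gene_partition()] covering the alignment.
#' @param removals named list: taxon name -> character vector of gene names
#'   to remove from that taxon.  Every taxon must retain at least one gene.
#' @return the modified [alignment()].
#' @export
remove_gene_blocks <- function(aln, part, removals) {
  validate_partition(part, aln$L)
  if (length(removals) == 0L) return(aln)
  if (is.null(names(removals)) || any(!nzchar(names(removals)))) {
    stop("`removals` must be a named list (taxon -> genes)")
  }
  unknown_taxa <- setdiff(names(removals), aln$labels)
  if (length(unknown_taxa)) {
    stop("unknown taxa: ", paste(unknown_taxa, collapse = ", "))
  }
  seqs <- aln$seqs
  names(seqs) <- aln$labels
  for (taxon in names(removals)) {
    genes <- as.character(removals[[taxon]])
    unknown <- setdiff(genes, part$gene)
    if (length(unknown)) {
      stop("unknown genes: ", paste(unknown, collapse = ", "))
    }
    if (all(part$gene %in% genes)) {
      stop(sprintf("removal would empty taxon '%s' entirely", taxon))
    }
    s <- strsplit(seqs[[taxon]], "")[[1]]
    for (g in genes) {
      row <- part[part$gene == g, ]
      s[row$start:row$end] <- "?"
    }
    seqs[[taxon]] <- paste(s, collapse = "")
  }
  alignment(aln$labels, unname(seqs))
}
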