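#' Multiple sequence alignment
#'
#' A light container for an aligned set of sequences: unique taxon labels
#' and equal-length character strings.  Nucleotide alignments use the
#' alphabet `A, C, G, T` plus gap `"-"` and missing `"?"`; amino-acid
#' alignments (accepted by the LogDet distance) use the 20 standard one
#' letter codes.  Ambiguity codes and any other character are treated as
#' missing data by all distance computations (pairwise deletion).
#'
#' @param labels character vector of unique taxon names.
#' @param seqs character vector of aligned sequences, one per taxon, all of
#'   the same length.  Stored upper-cased.
#' @return An object of class `"aln"` with elements `labels`, `seqs` and
#'   the alignment length `L`.
#' @export
alignment <- function(labels, seqs) {
  labels <- as.character(labels)
  seqs <- toupper(as.character(seqs))
  if (length(labels) != length(seqs)) stop("one sequence per label required")
  if (anyDuplicated(labels)) stop("duplicate taxon labels")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have identical length")
  if (L < 1L) stop("alignment length must be >= 1")
  structure(list(labels = labels, seqs = seqs, L = L), class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("Alignment: %d taxa, %d sites\n", length(x$labels), x$L))
  invisible(x)
}

#' Read / write plain FASTA alignments
#'
#' Thin wrappers around seqinr's FASTA parser and writer.  Wrapped (multi
#' line) records are supported; sequence case is normalised to upper case.
#'
#' @param path file path.
#' @return `read_fasta()` returns an [alignment()].
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  alignment(names(recs), vapply(recs, as.character, character(1)))
}

#' @param aln an [alignment()].
#' @rdname read_fasta
#' @return `write_fasta()` returns `path` invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqinr::write.fasta(as.list(aln$seqs), names = aln$labels, file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Gene partition of a concatenated alignment
#'
#' Maps gene names to contiguous, non-overlapping 1-based inclusive site
#' intervals.  When used against an alignment the intervals must be
#' ordered, disjoint and jointly cover sites `1..L`.
#'
#' @param gene character vector of gene names.
#' @param start,end integer vectors of interval bounds (1-based inclusive).
#' @return a data frame of class `"gene_partition"`.
#' @export
gene_partition <- function(gene, start, end) {
  part <- data.frame(gene = as.character(gene), start = as.integer(start),
                     end = as.integer(end), stringsAsFactors = FALSE)
  if (anyDuplicated(part$gene)) stop("duplicate gene names")
  if (any(part$end < part$start)) stop("interval end before start")
  part <- part[order(part$start), , drop = FALSE]
  rownames(part) <- NULL
  class(part) <- c("gene_partition", "data.frame")
  part
}

# Check that a partition tiles the alignment exactly.
validate_partition <- function(part, L) {
  if (part$start[1] != 1L) stop("partition must start at site 1")
  if (part$end[nrow(part)] != L) stop("partition must end at site L")
  if (nrow(part) > 1L &&
      any(part$start[-1] != part$end[-nrow(part)] + 1L)) {
    stop("partition intervals must be disjoint and contiguous")
  }
  invisible(part)
}

#' Read / write gene partition tables
#'
#' The on-disk format is a headerless TSV with columns
#' `gene<TAB>start<TAB>end`, 1-based inclusive.
#'
#' @param path file path.
#' @return `read_partition()` returns a [gene_partition()].
#' @export
read_partition <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "start", "end"),
                           stringsAsFactors = FALSE)
  gene_partition(tab$gene, tab$start, tab$end)
}

#' @param part a [gene_partition()].
#' @rdname read_partition
#' @export
write_partition <- function(part, path) {
  utils::write.table(as.data.frame(part), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
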