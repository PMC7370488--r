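#' Masked distance matrix
#'
#' The central data structure of the package: a symmetric matrix of pairwise
#' evolutionary distances between `N` taxa together with a symmetric logical
#' mask flagging the entries that are missing.  Distances are in expected
#' substitutions per site when estimated from sequences, or in arbitrary
#' additive units for synthetic matrices.
#'
#' Invariants enforced by the constructor:
#' * `values` and `mask` are `N x N` and symmetric; the diagonal of `values`
#'   is 0 and the diagonal of `mask` is `FALSE` (a taxon's self-distance is
#'   never missing).
#' * every observed off-diagonal value is finite and non-negative.
#' * labels are unique, non-empty, whitespace-free strings.
#'
#' Values stored under masked cells are ignored by all consumers except the
#' evaluation helpers: [delete_random_entries()] deliberately retains the
#' pre-deletion values under the new mask so that imputation error can be
#' measured, but [write_dist_matrix()] never emits them.
#'
#' @param values numeric `N x N` matrix of pairwise distances.  Cells that
#'   are masked may hold `NA`.
#' @param mask logical `N x N` matrix, `TRUE` where the distance is missing.
#'   Defaults to marking exactly the `NA` cells of `values`.
#' @param labels character vector of taxon names; defaults to
#'   `rownames(values)`.
#' @return An object of class `"masked_dist"`: a list with elements
#'   `labels`, `values` and `mask`.
#' @examples
#' v <- matrix(c(0, 1, 2, 1, 0, NA, 2, NA, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' m <- masked_dist_matrix(v)
#' missing_count(m)  # 1
#' @seealso [read_dist_matrix()], [write_dist_matrix()], [missing_count()]
#' @export
masked_dist_matrix <- function(values, mask = NULL, labels = rownames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  n <- nrow(values)
  if (ncol(values) != n) stop("`values` must be square")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  labels <- as.character(labels)
  if (is.null(mask)) mask <- is.na(values)
  if (!is.matrix(mask) || !is.logical(mask) ||
      nrow(mask) != n || ncol(mask) != n) {
    stop("`mask` must be a logical matrix of the same dimension as `values`")
  }
  dimnames(values) <- list(labels, labels)
  dimnames(mask) <- list(labels, labels)
  out <- structure(list(labels = labels, values = values, mask = mask),
                   class = "masked_dist")
  validate_masked_dist(out)
}

#' Validate a masked distance matrix
#'
#' Checks every type invariant and stops with an informative error on the
#' first violation.  Returns its argument invisibly changed (so it can be
#' used as the last step of a constructor).
#'
#' @param m a `"masked_dist"` object.
#' @return `m`, invisibly validated.
#' @export
validate_masked_dist <- function(m) {
  labels <- m$labels; values <- m$values; mask <- m$mask
  n <- length(labels)
  if (anyDuplicated(labels)) stop("duplicate taxon labels")
  if (any(!nzchar(labels)) || any(grepl("\\s", labels))) {
    stop("labels must be non-empty and whitespace-free")
  }
  if (any(diag(mask))) stop("diagonal entries cannot be missing")
  if (!isTRUE(all(diag(values) == 0))) stop("diagonal of `values` must be 0")
  if (!identical(mask, t(mask))) stop("`mask` must be symmetric")
  obs <- !mask & upper.tri(mask)
  v <- values[obs]
  if (anyNA(v) || any(!is.finite(v))) {
    stop("observed distances must be finite (use the mask for missing values)")
  }
  if (any(v < 0)) stop("observed distances must be non-negative")
  asym <- abs(values - t(values))
  asym[mask | is.na(asym)] <- 0
  if (max(asym) > 1e-9) stop("`values` must be symmetric on observed cells")
  m
}

#' @export
print.masked_dist <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("Masked distance matrix: %d taxa, %d/%d pairs missing\n",
              n, missing_count(x), n * (n - 1) / 2))
  invisible(x)
}

#' Number of taxa in a masked distance matrix
#' @param m a `"masked_dist"` object.
#' @return integer count of taxa.
#' @export
n_taxa <- function(m) length(m$labels)

#' Number of missing taxon pairs
#'
#' Each missing pair is masked at both `(i, j)` and `(j, i)`, so this is
#' `sum(mask) / 2` and always an integer between 0 and `N(N-1)/2`.
#'
#' @param m a `"masked_dist"` object.
#' @return integer count of distinct missing unordered pairs.
#' @export
missing_count <- function(m) as.integer(sum(m$mask) / 2)

#' Is the matrix complete (no missing entries)?
#' @param m a `"masked_dist"` object.
#' @return `TRUE` if the mask is empty.
#' @export
is_complete <- function(m) !any(m$mask)

#' Read a square distance matrix with missing-value markers
#'
#' Reads the package's relaxed square PHYLIP-like dialect: a first line with
#' the number of taxa `N`, then `N` whitespace-separated rows of
#' `label v1 ... vN`.  The token `missing_marker` (default `"NA"`) denotes a
#' missing entry.  Labels may be any whitespace-free string (no 10-character
#' truncation); lower-triangular input is not accepted.
#'
#' @param path path to the matrix file.
#' @param missing_marker token marking missing entries.
#' @param symmetrize if `TRUE`, repair asymmetric input by averaging
#'   observed `(i, j)`/`(j, i)` pairs and masking half-missing pairs on both
#'   sides; if `FALSE` (default) such input is rejected.
#' @return a [masked_dist_matrix()].
#' @export
read_dist_matrix <- function(path, missing_marker = "NA", symmetrize = FALSE) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty matrix file: ", path)
  n <- suppressWarnings(as.integer(strsplit(lines[[1]], "\\s+")[[1]][1]))
  if (is.na(n) || n < 1L) stop("first line must give the number of taxa")
  if (length(lines) != n + 1L) {
    stop(sprintf("expected %d matrix rows, found %d", n, length(lines) - 1L))
  }
  labels <- character(n)
  values <- matrix(NA_real_, n, n)
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(lines[[i + 1L]], "\\s+")[[1]]
    if (length(tok) != n + 1L) {
      stop(sprintf("row %d has %d values, expected %d (non-square input)",
                   i, length(tok) - 1L, n))
    }
    labels[i] <- tok[1]
    miss <- tok[-1] == missing_marker
    if (miss[i]) stop(sprintf("missing marker on the diagonal (row %d)", i))
    v <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(v[!miss])) stop(sprintf("non-numeric value in row %d", i))
    values[i, !miss] <- v[!miss]
    mask[i, miss] <- TRUE
  }
  if (anyDuplicated(labels)) stop("duplicate taxon labels")
  # Pair-level symmetry checks before handing off to the constructor.
  half <- mask != t(mask)
  both <- !mask & !t(mask)
  dev <- abs(values - t(values))
  dev[!both | is.na(dev)] <- 0
  if (any(half) || max(dev) > 1e-9) {
    if (!symmetrize) {
      stop("asymmetric input (use `symmetrize = TRUE` to repair)")
    }
    values[both] <- ((values + t(values)) / 2)[both]
    mask <- mask | t(mask)
    values[mask] <- NA_real_
  }
  neg <- values < 0 & !mask
  if (any(neg, na.rm = TRUE)) stop("negative observed distance")
  diag(values) <- 0
  masked_dist_matrix(values, mask, labels)
}

#' Write a masked distance matrix
#'
#' Inverse of [read_dist_matrix()]: emits the square dialect with observed
#' values at full precision (17 significant digits, so a round trip is exact
#' to well beyond 12 significant digits) and `missing_marker` in every
#' masked cell.  Values retained under the mask for evaluation purposes are
#' never emitted.
#'
#' @param m a `"masked_dist"` object.
#' @param path output file path.
#' @param missing_marker token to write in missing cells.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(m, path, missing_marker = "NA") {
  validate_masked_dist(m)
  n <- n_taxa(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  for (i in seq_len(n)) {
    cells <- vapply(seq_len(n), function(j) {
      if (m$mask[i, j]) missing_marker else sprintf("%.17g", m$values[i, j])
    }, character(1))
    writeLines(paste(c(m$labels[i], cells), collapse = " "), con)
  }
  invisible(path)
}

#' Complete a matrix by filling missing cells with the observed mean
#'
#' Baseline imputation used for benchmarking: every missing entry is set to
#' the mean of the observed off-diagonal distances.  Observed entries are
#' untouched.
#'
#' @param m a `"masked_dist"` object with at least one observed
#'   off-diagonal entry.
#' @return a complete `"masked_dist"` (empty mask).
#' @export
mean_fill_impute <- function(m) {
  validate_masked_dist(m)
  if (is_complete(m)) return(m)
  obs <- !m$mask & upper.tri(m$mask)
  if (!any(obs)) stop("no observed off-diagonal entries to average")
  fill <- mean(m$values[obs])
  v <- m$values
  v[m$mask] <- fill
  diag(v) <- 0
  masked_dist_matrix(v, matrix(FALSE, nrow(v), ncol(v)), m$labels)
}
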