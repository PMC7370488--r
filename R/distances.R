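#' @name distances
#' @title Pairwise evolutionary distances with pairwise deletion
#'
#' @description
#' Distance estimators used throughout the package.  Both operate on the
#' sites shared by a pair of sequences (pairwise deletion: any site where
#' either sequence carries a gap, `?`, or an ambiguity code is dropped for
#' that pair) and return `NA` — the "missing" value — whenever the estimate
#' is undefined, rather than raising an error.
#'
#' **TN93.**  The Tamura–Nei (1993) model distinguishes the two transition
#' classes (A<->G among purines, C<->T among pyrimidines) from
#' transversions.  With pooled base frequencies \eqn{\pi} estimated from
#' both sequences over their shared sites, purine/pyrimidine totals
#' \eqn{\pi_R, \pi_Y}, observed proportions \eqn{P_1} (A<->G), \eqn{P_2}
#' (C<->T) and \eqn{Q} (transversions), the closed-form distance is
#' \deqn{d = -\frac{2\pi_A\pi_G}{\pi_R}\ln w_1
#'           -\frac{2\pi_T\pi_C}{\pi_Y}\ln w_2
#'           -2\Big(\pi_R\pi_Y - \frac{\pi_A\pi_G\pi_Y}{\pi_R}
#'                - \frac{\pi_T\pi_C\pi_R}{\pi_Y}\Big)\ln w_3}
#' with \eqn{w_1 = 1 - \pi_R P_1/(2\pi_A\pi_G) - Q/(2\pi_R)},
#' \eqn{w_2 = 1 - \pi_Y P_2/(2\pi_T\pi_C) - Q/(2\pi_Y)} and
#' \eqn{w_3 = 1 - Q/(2\pi_R\pi_Y)}.  The estimate is missing when there are
#' no shared sites, when any required frequency product is zero, or when a
#' log argument is non-positive (saturation).
#'
#' **LogDet.**  Let \eqn{F} be the \eqn{K \times K} divergence matrix whose
#' \eqn{(i, j)} entry is the proportion of shared sites with state \eqn{i}
#' in the first sequence and \eqn{j} in the second (\eqn{K = 4} for
#' nucleotides, \eqn{K = 20} for amino acids).  The distance is
#' \eqn{d = -\ln \det F}, missing when there are no shared sites or
#' \eqn{\det F \le 0}.  LogDet is robust to base-composition shifts between
#' lineages.
#'
#' Both estimators are exactly symmetric in their two arguments (the base
#' frequencies are pooled, and \eqn{\det F^T = \det F}).
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T")
.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Encode a sequence string as integer codes 1..K; anything outside the
# alphabet (gap, ?, ambiguity codes) becomes 0 = missing.
encode_seq <- function(s, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  ab <- if (alphabet == "dna") .DNA_ALPHABET else .AA_ALPHABET
  v <- strsplit(toupper(s), "")[[1]]
  m <- match(v, ab)
  m[is.na(m)] <- 0L
  m
}

#' Sites shared by two aligned sequences
#'
#' Pairwise deletion: returns the (1-based) indices of sites where both
#' sequences carry an unambiguous alphabet symbol.
#'
#' @param x,y aligned sequences (character strings of equal length).
#' @param alphabet `"dna"` or `"protein"`.
#' @return integer vector of shared site indices (possibly empty).
#' @examples
#' shared_sites("AC?G", "A-CG")  # 1 4
#' @export
shared_sites <- function(x, y, alphabet = "dna") {
  cx <- encode_seq(x, alphabet)
  cy <- encode_seq(y, alphabet)
  if (length(cx) != length(cy)) stop("sequences must have equal length")
  which(cx > 0L & cy > 0L)
}

tn93_from_codes <- function(cx, cy, min_shared = 1L) {
  sh <- cx > 0L & cy > 0L
  ns <- sum(sh)
  if (ns < max(1L, min_shared)) return(NA_real_)
  x <- cx[sh]; y <- cy[sh]
  counts <- tabulate(x, 4L) + tabulate(y, 4L)
  p <- counts / (2 * ns)
  piA <- p[1]; piC <- p[2]; piG <- p[3]; piT <- p[4]
  piR <- piA + piG
  piY <- piC + piT
  if (piA * piG == 0 || piT * piC == 0 || piR == 0 || piY == 0) {
    return(NA_real_)
  }
  P1 <- sum((x == 1L & y == 3L) | (x == 3L & y == 1L)) / ns
  P2 <- sum((x == 2L & y == 4L) | (x == 4L & y == 2L)) / ns
  Q <- sum(x != y) / ns - P1 - P2
  w1 <- 1 - piR * P1 / (2 * piA * piG) - Q / (2 * piR)
  w2 <- 1 - piY * P2 / (2 * piT * piC) - Q / (2 * piY)
  w3 <- 1 - Q / (2 * piR * piY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  d <- -2 * piA * piG / piR * log(w1) -
    2 * piT * piC / piY * log(w2) -
    2 * (piR * piY - piA * piG * piY / piR - piT * piC * piR / piY) * log(w3)
  d + 0  # normalizes IEEE -0 from log(1) terms
}

logdet_from_codes <- function(cx, cy, K, min_shared = 1L) {
  sh <- cx > 0L & cy > 0L
  ns <- sum(sh)
  if (ns < max(1L, min_shared)) return(NA_real_)
  tab <- tabulate((cx[sh] - 1L) * K + cy[sh], K * K)
  Fxy <- matrix(tab, K, K, byrow = TRUE) / ns
  d <- det(Fxy)
  if (!is.finite(d) || d <= 0) return(NA_real_)
  -log(d)
}

#' @param x,y aligned sequences (character strings of equal length,
#'   nucleotide alphabet).
#' @param min_shared minimum number of shared sites required to call a
#'   distance; below it the result is `NA`.
#' @return a non-negative distance in substitutions per site, or `NA` when
#'   undefined (no shared sites, zero frequency products, saturation).
#' @rdname distances
#' @export
tn93_distance <- function(x, y, min_shared = 1L) {
  cx <- encode_seq(x, "dna")
  cy <- encode_seq(y, "dna")
  if (length(cx) != length(cy)) stop("sequences must have equal length")
  bad <- setdiff(unique(strsplit(toupper(paste0(x, y)), "")[[1]]),
                 c(.DNA_ALPHABET, "-", "?", "N", "U", "R", "Y", "S", "W",
                   "K", "M", "B", "D", "H", "V"))
  if (length(bad)) stop("non-nucleotide characters: ", paste(bad, collapse = ""))
  tn93_from_codes(cx, cy, min_shared)
}

#' @param alphabet for [logdet_distance()], `"dna"` (`K = 4`) or
#'   `"protein"` (`K = 20`).
#' @rdname distances
#' @export
logdet_distance <- function(x, y, alphabet = c("dna", "protein"),
                            min_shared = 1L) {
  alphabet <- match.arg(alphabet)
  cx <- encode_seq(x, alphabet)
  cy <- encode_seq(y, alphabet)
  if (length(cx) != length(cy)) stop("sequences must have equal length")
  K <- if (alphabet == "dna") 4L else 20L
  logdet_from_codes(cx, cy, K, min_shared)
}

#' Distance matrix from an alignment
#'
#' Evaluates the chosen estimator once for every unordered pair of taxa.
#' Pairs whose distance is undefined (for example because gene removal left
#' them with no shared homologous sites) become masked entries of the
#' resulting [masked_dist_matrix()]; the diagonal is 0 and never missing.
#'
#' @param aln an [alignment()].
#' @param model `"tn93"` (nucleotide) or `"logdet"`.
#' @param alphabet alphabet for the LogDet model.
#' @param min_shared minimum shared sites to call a distance.
#' @return a [masked_dist_matrix()] over the alignment's taxa.
#' @export
alignment_to_matrix <- function(aln, model = c("tn93", "logdet"),
                                alphabet = "dna", min_shared = 1L) {
  model <- match.arg(model)
  n <- length(aln$labels)
  if (n < 2L) stop("at least 2 taxa required")
  if (model == "tn93") alphabet <- "dna"
  K <- if (alphabet == "dna") 4L else 20L
  codes <- lapply(aln$seqs, encode_seq, alphabet = alphabet)
  values <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- if (model == "tn93") {
        tn93_from_codes(codes[[i]], codes[[j]], min_shared)
      } else {
        logdet_from_codes(codes[[i]], codes[[j]], K, min_shared)
      }
      if (is.na(d)) {
        mask[i, j] <- mask[j, i] <- TRUE
        values[i, j] <- values[j, i] <- NA_real_
      } else {
        # Clamp tiny negative estimates caused by sampling noise near d = 0.
        values[i, j] <- values[j, i] <- max(0, d)
      }
    }
  }
  masked_dist_matrix(values, mask, aln$labels)
}
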