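# Pairwise peptide sequence similarity: BLOSUM62 position sums,
# entropy-weighted substitution-matrix scores, and Hamming distance.

check_equal_length <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop(sprintf("length mismatch: '%s' has %d residues, '%s' has %d",
                 a, nchar(a), b, nchar(b)))
  }
}

#' Hamming distance between two peptides
#'
#' The number of positions at which two equal-length sequences differ;
#' e.g. AAAA and AAAB differ only at position 4, so their Hamming distance
#' is 1.
#'
#' @param a,b Peptide sequences of equal length.
#' @return Integer in `[0, nchar(a)]`.
#' @export
#' @examples
#' hamming("AAAA", "AAAB")
hamming <- function(a, b) {
  check_equal_length(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' BLOSUM62 peptide similarity
#'
#' Sum over positions of the BLOSUM62 value of the residue pair at that
#' position, optionally weighted per position.
#'
#' @param a,b Peptide sequences of equal length, standard residues.
#' @param position_weights Optional numeric vector of per-position weights
#'   (defaults to 1 at every position); see [entropy_position_weights()].
#' @param matrix Substitution matrix (defaults to [blosum62()]).
#' @return Numeric similarity; higher means more similar.
#' @export
blosum62_similarity <- function(a, b, position_weights = NULL,
                                matrix = blosum62()) {
  check_equal_length(a, b)
  la <- check_standard_residues(a)
  lb <- check_standard_residues(b)
  w <- check_position_weights(position_weights, length(la))
  sum(w * matrix[cbind(la, lb)])
}

check_position_weights <- function(w, L) {
  if (is.null(w)) return(rep(1, L))
  if (inherits(w, "position_weights")) w <- w$weights
  if (length(w) != L) {
    stop(sprintf("position weights have length %d but peptides have %d positions",
                 length(w), L))
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("position weights must be finite and non-negative")
  }
  w
}

#' Entropy-derived peptide position weights
#'
#' Computes the Shannon entropy (bits) of each peptide column over the
#' whole dataset and converts it to a conservation weight
#' `w_p = (log2(20) - H_p) / log2(20)`, clipped to \[0, 1\]: fully
#' conserved columns get weight 1, maximally diverse columns weight 0.
#'
#' @param peptides Character vector of >= 2 equal-length sequences.
#' @return An object of class `position_weights` with fields `weights` and
#'   `source = "entropy"`.
#' @export
entropy_position_weights <- function(peptides) {
  if (length(peptides) < 2) stop("need at least 2 peptides")
  L <- unique(nchar(peptides))
  if (length(L) > 1) {
    stop("mixed peptide lengths: ", paste(L, collapse = ", "))
  }
  cols <- do.call(rbind, strsplit(peptides, ""))
  hmax <- log2(20)
  H <- apply(cols, 2, function(col) {
    f <- table(col) / length(col)
    -sum(f * log2(f))
  })
  w <- pmin(1, pmax(0, (hmax - H) / hmax))
  structure(list(weights = unname(w), source = "entropy"),
            class = "position_weights")
}

#' Entropy-weighted substitution-matrix peptide similarity
#'
#' Sum over positions of `w_p * M(a_p, b_p)` where `M` is a PMBEC-style
#' amino-acid similarity matrix and `w_p` the per-position weights
#' (typically from [entropy_position_weights()]). The bundled default
#' matrix is the synthetic surrogate [pmbec_surrogate()]; supply the
#' published PMBEC table via [read_substitution_matrix()] for exact
#' reproduction.
#'
#' @inheritParams blosum62_similarity
#' @param weights Per-position weights ([entropy_position_weights()] output
#'   or numeric vector).
#' @return Numeric similarity; higher means more similar.
#' @export
pmbec_weighted_similarity <- function(a, b, weights,
                                      matrix = pmbec_surrogate()) {
  blosum62_similarity(a, b, position_weights = weights, matrix = matrix)
}

#' Pairwise sequence similarity matrices
#'
#' Computes the three sequence components for a peptide set: BLOSUM62
#' position-sum similarity, entropy-weighted PMBEC-style similarity
#' (HLAthena-like component), and Hamming distance, all over a consistent
#' id ordering.
#'
#' @param peptides Character vector of >= 2 equal-length sequences.
#' @param ids Optional ids (default the peptides themselves).
#' @param position_weights Optional user weights for the PMBEC-style
#'   component; default is [entropy_position_weights()] over `peptides`.
#' @param pmbec_matrix Substitution matrix for the weighted component.
#' @return A named list of three [pepsim_matrix()] objects: `blosum62` and
#'   `hlathena` (orientation "similarity") and `hamming` (orientation
#'   "distance").
#' @export
sequence_matrices <- function(peptides, ids = peptides,
                              position_weights = NULL,
                              pmbec_matrix = pmbec_surrogate()) {
  if (length(peptides) < 2) stop("need at least 2 peptides")
  lens <- nchar(peptides)
  if (length(unique(lens)) > 1) {
    off <- peptides[lens != stats::median(lens)]
    stop("mixed peptide lengths; offending peptides: ",
         paste(off, collapse = ", "))
  }
  if (anyDuplicated(ids)) stop("peptide ids must be unique")
  w <- if (is.null(position_weights)) {
    entropy_position_weights(peptides)
  } else {
    position_weights
  }
  n <- length(peptides)
  b62 <- blosum62()
  pairwise <- function(f) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
      for (j in i:n) {
        m[i, j] <- m[j, i] <- f(peptides[i], peptides[j])
      }
    }
    m
  }
  list(
    blosum62 = pepsim_matrix(
      pairwise(function(a, b) blosum62_similarity(a, b, matrix = b62)),
      component = "blosum62", orientation = "similarity"),
    hlathena = pepsim_matrix(
      pairwise(function(a, b) {
        pmbec_weighted_similarity(a, b, w, matrix = pmbec_matrix)
      }),
      component = "hlathena", orientation = "similarity"),
    hamming = pepsim_matrix(
      pairwise(hamming), component = "hamming", orientation = "distance")
  )
}
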