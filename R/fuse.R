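# Similarity matrix container, z-normalization, and component fusion.

#' Pairwise similarity/distance matrix
#'
#' Square symmetric matrix of pairwise scores for one component of the
#' fused score (or the fused score itself), with an explicit orientation:
#' `"similarity"` (high = similar; BLOSUM62, PMBEC components) or
#' `"distance"` (low = similar; Hamming, structural, fused).
#'
#' @param scores Square numeric matrix; dimnames carry the peptide ids
#'   unless `ids` is given.
#' @param component One of `"blosum62"`, `"hlathena"`, `"hamming"`,
#'   `"structural"`, `"fused"`.
#' @param orientation `"similarity"` or `"distance"`.
#' @param ids Optional character vector of unique peptide ids.
#' @return An object of class `pepsim_matrix` (a numeric matrix with
#'   attributes `component` and `orientation`).
#' @export
pepsim_matrix <- function(scores, component, orientation,
                          ids = rownames(scores)) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n != ncol(scores)) stop("scores must be square")
  if (is.null(ids)) ids <- paste0("p", seq_len(n))
  if (anyDuplicated(ids)) stop("ids must be unique")
  orientation <- match.arg(orientation, c("similarity", "distance"))
  asym <- max(abs(scores - t(scores)))
  if (asym > 1e-9) {
    stop("matrix is not symmetric (max asymmetry ", format(asym), ")")
  }
  scores <- (scores + t(scores)) / 2
  dimnames(scores) <- list(ids, ids)
  structure(scores, component = component, orientation = orientation,
            class = c("pepsim_matrix", "matrix", "array"))
}

matrix_ids <- function(m) rownames(m)

#' @exportS3Method base::as.matrix
as.matrix.pepsim_matrix <- function(x, ...) {
  y <- unclass(x)
  attr(y, "component") <- NULL
  attr(y, "orientation") <- NULL
  y
}

#' @export
print.pepsim_matrix <- function(x, ...) {
  cat(sprintf("<pepsim_matrix> %s (%s), %d x %d\n", attr(x, "component"),
              attr(x, "orientation"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))),
                   drop = FALSE])
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Tidy a pairwise matrix into long form
#'
#' @param x A [pepsim_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `id1`, `id2`, `score`, `component`,
#'   `orientation` (one row per ordered pair).
#' @export
tidy.pepsim_matrix <- function(x, ...) {
  ids <- matrix_ids(x)
  tibble::tibble(
    id1 = rep(ids, times = length(ids)),
    id2 = rep(ids, each = length(ids)),
    score = as.numeric(unclass(x)),
    component = attr(x, "component"),
    orientation = attr(x, "orientation")
  )
}

#' Write a pairwise matrix as CSV
#'
#' @param x A [pepsim_matrix()].
#' @param path Output path; ids form the header row and first column.
#' @export
write_matrix_csv <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' Z-normalize a score matrix
#'
#' Subtracts the mean of all n^2 cells (diagonal included) and divides by
#' the population standard deviation, so the output has mean 0 and
#' population SD 1.
#'
#' @param matrix A [pepsim_matrix()] with at least 2 distinct values.
#' @return A [pepsim_matrix()] with the same component and orientation.
#' @export
znorm <- function(matrix) {
  v <- as.numeric(unclass(matrix))
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (sdev < 1e-12) {
    stop("degenerate component: matrix '", attr(matrix, "component"),
         "' is constant")
  }
  pepsim_matrix((unclass(matrix) - mu) / sdev,
                component = attr(matrix, "component"),
                orientation = attr(matrix, "orientation"))
}

#' Fuse z-normalized component matrices
#'
#' Element-wise weighted sum of z-normalized components into the fused
#' score. Similarity-oriented components are negated before summation so
#' that the fused matrix is distance-oriented: a low fused score means a
#' more similar pHLA pair.
#'
#' @param matrices List of z-normalized [pepsim_matrix()] objects with
#'   identical id orderings.
#' @param weights Named or positional numeric weights, one per matrix
#'   (default 1 each). All-zero weights are an error.
#' @return A [pepsim_matrix()] with component `"fused"` and orientation
#'   `"distance"`.
#' @export
combine <- function(matrices, weights = NULL) {
  if (length(matrices) == 0) stop("no component matrices supplied")
  ids <- matrix_ids(matrices[[1]])
  for (m in matrices) {
    if (!identical(matrix_ids(m), ids)) {
      stop("component matrices have mismatched id orderings")
    }
  }
  if (is.null(weights)) weights <- rep(1, length(matrices))
  if (!is.null(names(weights)) && !is.null(names(matrices))) {
    weights <- weights[names(matrices)]
  }
  if (length(weights) != length(matrices) || any(!is.finite(weights))) {
    stop("need one finite weight per component matrix")
  }
  if (all(weights == 0)) stop("all component weights are zero")
  acc <- matrix(0, length(ids), length(ids))
  for (k in seq_along(matrices)) {
    sgn <- if (attr(matrices[[k]], "orientation") == "similarity") -1 else 1
    acc <- acc + weights[k] * sgn * unclass(matrices[[k]])
  }
  pepsim_matrix(acc, component = "fused", orientation = "distance",
                ids = ids)
}
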