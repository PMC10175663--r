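# Evaluation of a fused similarity matrix: agglomerative clustering,
# leave-one-out k-nearest-neighbour validation, confusion metrics, target
# ranking and a 2D NMDS embedding.

# hclust/metaMDS need non-negative dissimilarities; the fused z-scored
# matrix is shifted by its minimum off-diagonal value and the diagonal is
# forced to zero. A constant shift preserves the ranking semantics.
as_nonneg_dist <- function(fused) {
  m <- unclass(fused)
  if (attr(fused, "orientation") != "distance") {
    stop("expected a distance-oriented matrix")
  }
  off <- m[row(m) != col(m)]
  m <- m - min(0, off)
  diag(m) <- 0
  m
}

#' Agglomerative clustering of a fused matrix
#'
#' Hierarchical clustering (Ward or average linkage) of the fused
#' distance-oriented matrix. With `n_clusters` set, the tree is cut into
#' that many groups; with `n_clusters = NULL` the full merge tree is
#' returned and can be exported as a Newick dendrogram with branch
#' heights.
#'
#' @param fused A distance-oriented [pepsim_matrix()] (>= 2 peptides).
#' @param linkage `"ward"` or `"average"`.
#' @param n_clusters Number of clusters, or NULL for the full tree.
#' @return A list with `labels` (named integer vector, NULL when
#'   `n_clusters` is NULL), `hclust` (the merge tree), and `newick` (the
#'   dendrogram as a Newick string with branch heights).
#' @export
cluster_agglomerative <- function(fused, linkage = c("ward", "average"),
                                  n_clusters = 2) {
  linkage <- match.arg(linkage)
  if (nrow(fused) < 2) stop("need >= 2 peptides to cluster")
  d <- stats::as.dist(as_nonneg_dist(fused))
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else "average")
  labels <- NULL
  if (!is.null(n_clusters)) {
    labels <- stats::cutree(hc, k = n_clusters)
  }
  list(labels = labels, hclust = hc, newick = hclust_to_newick(hc),
       linkage = linkage)
}

hclust_to_newick <- function(hc) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}

#' Leave-one-out k-nearest-neighbour validation
#'
#' For each peptide and each k, predicts its label from the majority label
#' of its k nearest neighbours (self excluded) in the fused matrix; split
#' votes at even k are resolved by the nearest neighbour's label.
#'
#' @param fused A distance-oriented [pepsim_matrix()].
#' @param labels Named logical vector (TRUE = cross-reactive positive)
#'   covering every id; may also be unnamed in matrix order.
#' @param k_values Integer vector of neighbourhood sizes (default 1:8).
#' @return A tibble with columns `k`, `sensitivity`, `specificity` (as
#'   proportions in \[0, 1\]), `tp`, `fp`, `tn`, `fn`.
#' @export
knn_loo_classify <- function(fused, labels, k_values = 1:8) {
  ids <- matrix_ids(fused)
  labels <- align_labels(labels, ids)
  n <- length(ids)
  if (max(k_values) >= n) stop("max k must be < number of peptides")
  m <- unclass(fused)
  purrr::map_dfr(k_values, function(k) {
    pred <- vapply(seq_len(n), function(i) {
      d <- m[i, -i]
      lab <- labels[-i]
      ord <- order(d, names(d))
      nb <- lab[ord[seq_len(k)]]
      votes <- sum(nb)
      if (votes * 2 == k) nb[1] else votes * 2 > k
    }, logical(1))
    conf <- confusion_counts(ids[pred], labels)
    tibble::tibble(k = k,
                   sensitivity = conf$tp / (conf$tp + conf$fn),
                   specificity = conf$tn / (conf$tn + conf$fp),
                   tp = conf$tp, fp = conf$fp, tn = conf$tn, fn = conf$fn)
  })
}

align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels))) {
      stop("labels missing for: ",
           paste(setdiff(ids, names(labels)), collapse = ", "))
    }
    labels <- labels[ids]
  } else {
    if (length(labels) != length(ids)) stop("one label per peptide required")
    names(labels) <- ids
  }
  if (any(is.na(labels))) stop("unlabeled peptide(s) present")
  labels
}

confusion_counts <- function(predicted_positive, labels) {
  pos <- names(labels)[labels]
  neg <- names(labels)[!labels]
  list(tp = sum(pos %in% predicted_positive),
       fn = sum(!pos %in% predicted_positive),
       fp = sum(neg %in% predicted_positive),
       tn = sum(!neg %in% predicted_positive))
}

#' Confusion metrics for a predicted cross-reactive set
#'
#' Computes TP/FP/TN/FN and sensitivity/specificity percentages
#' (`100 * TP / (TP + FN)` and `100 * TN / (TN + FP)`, reported to two
#' decimals) for a predicted-positive peptide set against boolean labels.
#' Because a 2-way clustering does not say which cluster is the
#' cross-reactive one, the given set and its complement are both evaluated
#' and the assignment maximising TP + TN is reported.
#'
#' @param predicted_positive Character vector of peptide ids predicted
#'   cross-reactive (e.g. one cluster).
#' @param labels Named logical vector over all ids (TRUE = cross-reactive).
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity` (percent, 2 decimals).
#' @export
#' @examples
#' labels <- c(stats::setNames(rep(TRUE, 3), c("a", "b", "c")),
#'             stats::setNames(rep(FALSE, 2), c("d", "e")))
#' confusion_metrics(c("a", "b", "c"), labels)
confusion_metrics <- function(predicted_positive, labels) {
  if (is.null(names(labels))) stop("labels must be named by peptide id")
  if (any(is.na(labels))) stop("unlabeled peptide(s) present")
  if (all(labels) || !any(labels)) {
    stop("labels must contain at least one positive and one negative")
  }
  ids <- names(labels)
  c1 <- confusion_counts(predicted_positive, labels)
  c2 <- confusion_counts(setdiff(ids, predicted_positive), labels)
  conf <- if (c2$tp + c2$tn > c1$tp + c1$tn) c2 else c1
  tibble::tibble(
    tp = conf$tp, fp = conf$fp, tn = conf$tn, fn = conf$fn,
    sensitivity = round(100 * conf$tp / (conf$tp + conf$fn), 2),
    specificity = round(100 * conf$tn / (conf$tn + conf$fp), 2)
  )
}

#' Rank peptides against a target
#'
#' Orders all non-target peptides by ascending fused score against the
#' target (low = most similar = most likely cross-reactive with it); ties
#' break lexicographically by id.
#'
#' @param fused A distance-oriented [pepsim_matrix()].
#' @param target A peptide id present in the matrix.
#' @return A tibble with columns `rank`, `peptide`, `score`.
#' @export
rank_targets <- function(fused, target) {
  ids <- matrix_ids(fused)
  if (!target %in% ids) {
    stop("unknown target '", target, "'; available ids: ",
         paste(ids, collapse = ", "))
  }
  s <- unclass(fused)[target, , drop = TRUE][setdiff(ids, target)]
  ord <- order(s, names(s))
  tibble::tibble(rank = seq_along(ord), peptide = names(s)[ord],
                 score = unname(s[ord]))
}

#' Non-metric multidimensional scaling of a fused matrix
#'
#' 2D NMDS embedding (vegan::metaMDS) of the shifted non-negative fused
#' distances; deterministic for a given seed.
#'
#' @param fused A distance-oriented [pepsim_matrix()] over >= 3 peptides.
#' @param seed Integer seed.
#' @return A tibble with columns `peptide`, `x`, `y`; the final stress is
#'   attached as attribute `"stress"`.
#' @export
nmds_embed <- function(fused, seed = 17L) {
  if (nrow(fused) < 3) stop("need >= 3 peptides for a 2D embedding")
  d <- stats::as.dist(as_nonneg_dist(fused))
  pts <- with_local_seed(seed, {
    fit <- suppressWarnings(
      vegan::metaMDS(d, k = 2, trace = 0, autotransform = FALSE,
                     wascores = FALSE))
    attr_stress <- fit$stress
    list(points = fit$points, stress = attr_stress)
  })
  out <- tibble::tibble(peptide = matrix_ids(fused),
                        x = pts$points[, 1], y = pts$points[, 2])
  attr(out, "stress") <- pts$stress
  out
}
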