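# End-to-end pipeline: complexes -> component matrices -> fused score ->
# clustering / KNN / ranking / embedding, bundled into a report object.

#' Run the full similarity pipeline
#'
#' Takes a set of peptide-HLA complexes (a manifest file path, a manifest
#' tibble from [read_manifest()], or a tibble with a `complex` list-column
#' such as [make_synthetic_dataset()] returns), computes the enabled
#' component matrices, z-normalizes and fuses them, and evaluates the
#' fused score: agglomerative 2-clustering, leave-one-out KNN (when labels
#' are present), ranking against a target (when given), and a 2D NMDS
#' embedding.
#'
#' The structural component pre-aligns every complex onto the first by its
#' HLA C-alpha atoms, builds and downsamples a surface mesh, annotates it,
#' and extracts the TCR-facing patch before pairwise ICP scoring.
#'
#' @param x Manifest path, manifest tibble, or tibble with columns
#'   `peptide`, optional `label`, and either `path` or `complex`.
#' @param target Optional target peptide id for ranking.
#' @param linkage `"ward"` or `"average"`.
#' @param components Character subset of
#'   `c("blosum62", "hlathena", "hamming", "structural")`.
#' @param weights Optional named numeric sub-score weights (default 1).
#' @param position_weights Optional per-position weights for the
#'   PMBEC-style component (default: entropy weights over the dataset).
#' @param icp [icp_config()] for the structural component.
#' @param n_clusters Number of clusters for the flat clustering.
#' @param k_values KNN neighbourhood sizes.
#' @param seed Seed for the NMDS embedding.
#' @param probe_radius,grid_spacing,resolution,max_edges Surface and patch
#'   parameters (Angstrom / edge hops).
#' @param surface_backend `"internal"` or `"external"` (MSMS binary).
#' @param out_dir Optional directory to write CSV/TSV/Newick/JSON outputs.
#' @param verbose Print progress messages.
#' @return An object of class `pepsim_report`; see [tidy.pepsim_report()]
#'   and [glance.pepsim_report()].
#' @export
pepsim_run <- function(x, target = NULL, linkage = "ward",
                       components = c("blosum62", "hlathena", "hamming",
                                      "structural"),
                       weights = NULL, position_weights = NULL,
                       icp = icp_config(), n_clusters = 2,
                       k_values = 1:8, seed = 17L,
                       probe_radius = 1.5, grid_spacing = 0.8,
                       resolution = 1.0, max_edges = 16,
                       surface_backend = "internal",
                       out_dir = NULL, verbose = FALSE) {
  components <- match.arg(components, several.ok = TRUE)
  ds <- load_dataset(x)
  ids <- ds$peptide
  say <- function(...) if (verbose) message(...)

  mats <- list()
  seq_components <- intersect(components, c("blosum62", "hlathena", "hamming"))
  if (length(seq_components) > 0) {
    say("sequence matrices for ", length(ids), " peptides")
    sm <- sequence_matrices(vapply(ds$complex, function(cpx)
      cpx$peptide_sequence, character(1)), ids = ids,
      position_weights = position_weights)
    mats <- sm[seq_components]
  }
  if ("structural" %in% components) {
    say("surface patches")
    clouds <- lapply(seq_along(ds$complex), function(i) {
      cpx <- ds$complex[[i]]
      if (i > 1) {
        cpx <- apply_transform_complex(cpx, prealign(ds$complex[[1]], cpx))
      }
      mesh <- build_surface_mesh(cpx, backend = surface_backend,
                                 probe_radius = probe_radius,
                                 grid_spacing = grid_spacing)
      mesh <- downsample_mesh(mesh, resolution)
      feats <- annotate_features(mesh, cpx)
      extract_patch(mesh, feats, cpx, max_edges = max_edges)
    })
    names(clouds) <- ids
    say("pairwise ICP")
    mats$structural <- structural_matrix(clouds, icp)
  }
  mats <- mats[order(match(names(mats), components))]

  say("fusing ", paste(names(mats), collapse = " + "))
  fused <- combine(lapply(mats, znorm),
                   weights = if (is.null(weights)) NULL else
                     weights[names(mats)])

  clust <- cluster_agglomerative(fused, linkage = linkage,
                                 n_clusters = n_clusters)
  labels <- if (!all(is.na(ds$label))) {
    stats::setNames(as.logical(ds$label), ids)
  } else {
    NULL
  }
  confusion <- NULL
  knn <- NULL
  if (!is.null(labels) && any(labels) && !any(is.na(labels)) && !all(labels)) {
    predicted <- names(clust$labels)[clust$labels == clust$labels[1]]
    # evaluate the cluster containing the first peptide; confusion_metrics
    # picks the class assignment maximising TP + TN
    confusion <- confusion_metrics(predicted, labels)
    kv <- k_values[k_values < length(ids)]
    if (length(kv) > 0) knn <- knn_loo_classify(fused, labels, kv)
  }
  ranking <- if (!is.null(target)) rank_targets(fused, target) else NULL
  embedding <- if (length(ids) >= 3) nmds_embed(fused, seed = seed) else NULL

  report <- structure(list(
    ids = ids, components = mats, fused = fused, linkage = linkage,
    cluster_labels = clust$labels, newick = clust$newick,
    hclust = clust$hclust, labels = labels, confusion = confusion,
    knn = knn, target = target, ranking = ranking, embedding = embedding,
    parameters = list(components = components, linkage = linkage,
                      n_clusters = n_clusters, probe_radius = probe_radius,
                      grid_spacing = grid_spacing, resolution = resolution,
                      max_edges = max_edges, epsilon = icp$epsilon,
                      feature_scaling = icp$feature_scaling, seed = seed)
  ), class = "pepsim_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

load_dataset <- function(x) {
  if (is.character(x) && length(x) == 1) x <- read_manifest(x)
  if (inherits(x, "data.frame")) {
    ds <- tibble::as_tibble(x)
    if (!"complex" %in% names(ds)) {
      if (!"path" %in% names(ds)) {
        stop("dataset needs a 'complex' or 'path' column")
      }
      ds$complex <- purrr::map2(ds$path, ds$peptide,
                                function(p, id) parse_phla_pdb(p, id = id))
    }
    if (!"peptide" %in% names(ds)) {
      ds$peptide <- vapply(ds$complex, function(cpx) cpx$id, character(1))
    }
    if (!"label" %in% names(ds)) ds$label <- NA
    return(ds)
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "phla_complex"))) {
    return(tibble::tibble(
      peptide = vapply(x, function(cpx) cpx$id, character(1)),
      label = NA, complex = x))
  }
  stop("cannot interpret dataset input")
}

#' @export
print.pepsim_report <- function(x, ...) {
  cat(sprintf("<pepsim_report> %d peptides; components: %s; linkage %s\n",
              length(x$ids), paste(names(x$components), collapse = ", "),
              x$linkage))
  if (!is.null(x$confusion)) {
    cat(sprintf("  2-cluster sensitivity %.2f%%, specificity %.2f%%\n",
                x$confusion$sensitivity, x$confusion$specificity))
  }
  if (!is.null(x$ranking)) {
    cat(sprintf("  top match for %s: %s (score %.3f)\n", x$target,
                x$ranking$peptide[1], x$ranking$score[1]))
  }
  invisible(x)
}

#' Tidy and summarise a pipeline report
#'
#' `tidy()` returns the per-peptide table (cluster label, true label,
#' embedding coordinates, rank against the target where available);
#' `glance()` returns a one-row summary (counts, confusion metrics,
#' best-k KNN performance, NMDS stress).
#'
#' @param x A `pepsim_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pepsim_report <- function(x, ...) {
  out <- tibble::tibble(peptide = x$ids,
                        cluster = unname(x$cluster_labels[x$ids]))
  if (!is.null(x$labels)) out$label <- unname(x$labels[x$ids])
  if (!is.null(x$embedding)) {
    out <- dplyr::left_join(out, x$embedding, by = "peptide")
  }
  if (!is.null(x$ranking)) {
    out <- dplyr::left_join(
      out, dplyr::select(x$ranking, peptide, rank, target_score = score),
      by = "peptide")
  }
  out
}

#' @rdname tidy.pepsim_report
#' @export
glance.pepsim_report <- function(x, ...) {
  out <- tibble::tibble(n_peptides = length(x$ids),
                        n_components = length(x$components),
                        linkage = x$linkage)
  if (!is.null(x$confusion)) {
    out$sensitivity <- x$confusion$sensitivity
    out$specificity <- x$confusion$specificity
  }
  if (!is.null(x$knn)) {
    best <- x$knn[which.max(x$knn$sensitivity + x$knn$specificity), ]
    out$knn_best_k <- best$k
    out$knn_sensitivity <- best$sensitivity
    out$knn_specificity <- best$specificity
  }
  if (!is.null(x$embedding)) out$stress <- attr(x$embedding, "stress")
  out
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_matrix_csv(report$fused, file.path(out_dir, "fused_matrix.csv"))
  for (nm in names(report$components)) {
    write_matrix_csv(report$components[[nm]],
                     file.path(out_dir, paste0(nm, "_matrix.csv")))
  }
  if (!is.null(report$ranking)) {
    utils::write.table(report$ranking, file.path(out_dir, "ranking.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines(report$newick, file.path(out_dir, "dendrogram.newick"))
  if (!is.null(report$embedding)) {
    utils::write.csv(report$embedding, file.path(out_dir, "embedding.csv"),
                     row.names = FALSE)
  }
  summary_list <- list(parameters = report$parameters,
                       peptides = report$ids,
                       cluster_labels = as.list(report$cluster_labels))
  if (!is.null(report$confusion)) {
    summary_list$confusion <- as.list(report$confusion)
  }
  if (!is.null(report$knn)) summary_list$knn <- report$knn
  jsonlite::write_json(summary_list, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
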