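# Structural similarity: Kabsch pre-alignment of complexes into a common
# frame, geometry-only iterative closest point between surface patches,
# and the six-dimensional D2 distance (xyz + electrostatics + hydrogen
# bonding + hydrophobicity) over the final correspondence set.

#' ICP configuration
#'
#' @param epsilon Correspondence cutoff in Angstrom: only source-target
#'   pairs within `epsilon` enter the corresponding set.
#' @param convergence_tol Stop when the change in the geometric distance D
#'   falls below this.
#' @param max_iterations Iteration cap.
#' @param feature_scaling `"zscore"` (z-score each feature column across
#'   the dataset before the 6D distance) or `"none"`.
#' @param coarse_init Start from centroid alignment with the
#'   correspondence gate annealed from the cloud diameter down to
#'   `epsilon` (halved each iteration). This is the standard
#'   coarse-to-fine remedy for registration from rough initial poses; the
#'   final correspondence set is always taken at `epsilon`, and pairs with
#'   no `epsilon`-correspondences at the initial pose are still flagged
#'   non-overlapping.
#' @return An object of class `icp_config`.
#' @export
icp_config <- function(epsilon = 2.0, convergence_tol = 1e-6,
                       max_iterations = 30,
                       feature_scaling = c("zscore", "none"),
                       coarse_init = TRUE) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(epsilon = epsilon, convergence_tol = convergence_tol,
                 max_iterations = max_iterations,
                 feature_scaling = match.arg(feature_scaling),
                 coarse_init = isTRUE(coarse_init)),
            class = "icp_config")
}

#' Pre-align two complexes on their HLA chains
#'
#' Least-squares (Kabsch) superposition of the C-alpha atoms of HLA
#' residues matched by author residue numbering. The returned transform
#' maps `moving` onto `reference`; applying it to meshes or clouds derived
#' from `moving` is the caller's responsibility.
#'
#' @param reference,moving [phla_complex()] objects sharing at least 50
#'   HLA residue numbers.
#' @return A [rigid_transform()].
#' @export
prealign <- function(reference, moving) {
  ca <- function(cpx) {
    a <- cpx$atoms
    a <- a[a$chain_id == cpx$hla_chain & a$name == "CA", , drop = FALSE]
    a[!duplicated(a$residue_index), , drop = FALSE]
  }
  ra <- ca(reference)
  ma <- ca(moving)
  shared <- intersect(ra$residue_index, ma$residue_index)
  if (length(shared) < 50) {
    stop("insufficient HLA overlap: ", length(shared),
         " matched residues (< 50)")
  }
  ri <- match(shared, ra$residue_index)
  mi <- match(shared, ma$residue_index)
  kabsch(as.matrix(ma[mi, c("x", "y", "z")]),
         as.matrix(ra[ri, c("x", "y", "z")]))
}

apply_transform_complex <- function(complex, transform) {
  xyz <- apply_transform(transform, as.matrix(complex$atoms[, c("x", "y", "z")]))
  complex$atoms$x <- xyz[, 1]
  complex$atoms$y <- xyz[, 2]
  complex$atoms$z <- xyz[, 3]
  complex
}

#' Iterative closest point registration
#'
#' Aligns a source point cloud to a target cloud with the classic
#' three-step iteration: (1) match each source point to its nearest target
#' point and keep pairs within `epsilon`; (2) solve the least-squares rigid
#' transform over the corresponding set (Kabsch), minimising
#' `D = sum ||S_i - T_j||^2`; (3) apply it. Iterates until `|delta D|` is
#' below the tolerance or the iteration cap. Alignment uses geometry only;
#' the biochemical features play no role here. If no pair falls within
#' `epsilon` at the first iteration, the pair is flagged non-overlapping
#' (`final_D = Inf`, empty correspondences) rather than erroring.
#'
#' @param source,target [feature_cloud()] objects (>= 4 points each),
#'   already pre-aligned to a common frame.
#' @param config An [icp_config()].
#' @return An object of class `icp_result`: `transform` (cumulative
#'   source-to-target [rigid_transform()]), `correspondences` (two-column
#'   matrix of source/target indices), `final_D` (summed squared 3D
#'   distances, Angstrom^2), `D_trace`, `iterations`, `converged`,
#'   `non_overlapping`.
#' @export
icp_align <- function(source, target, config = icp_config()) {
  if (nrow(source$points) < 4 || nrow(target$points) < 4) {
    stop("both clouds need >= 4 points")
  }
  S <- source$points
  Tm <- target$points
  # overlap test at the initial pose: no pair within epsilon means the
  # clouds cannot be registered under the epsilon-ball rule
  j0 <- nn_index(S, Tm)
  if (!any(rowSums((S - Tm[j0, , drop = FALSE])^2) <= config$epsilon^2)) {
    return(structure(list(transform = rigid_transform(),
                          correspondences = matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("source", "target"))),
                          final_D = Inf, D_trace = numeric(0),
                          D_pre_trace = numeric(0), iterations = 0,
                          converged = FALSE, non_overlapping = TRUE),
                     class = "icp_result"))
  }
  total <- rigid_transform()
  if (config$coarse_init) {
    shift <- colMeans(Tm) - colMeans(S)
    total <- rigid_transform(diag(3), shift)
    S <- sweep(S, 2, shift, "+")
    diameter <- sqrt(max(rowSums(sweep(Tm, 2, colMeans(Tm))^2))) * 2
  }
  D_prev <- Inf
  D_trace <- numeric(0)
  D_pre_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < config$max_iterations) {
    iter <- iter + 1
    eps_it <- if (config$coarse_init) {
      max(config$epsilon, diameter * 0.5^(iter - 1))
    } else {
      config$epsilon
    }
    j <- nn_index(S, Tm)
    d2 <- rowSums((S - Tm[j, , drop = FALSE])^2)
    keep <- which(d2 <= eps_it^2)
    if (length(keep) == 0) break
    D_pre_trace <- c(D_pre_trace, sum(d2[keep]))
    tf <- kabsch(S[keep, , drop = FALSE], Tm[j[keep], , drop = FALSE])
    S <- apply_transform(tf, S)
    total <- compose_transforms(tf, total)
    D <- sum(rowSums((S[keep, , drop = FALSE] -
                        Tm[j[keep], , drop = FALSE])^2))
    D_trace <- c(D_trace, D)
    if (is.finite(D_prev) && eps_it <= config$epsilon &&
        abs(D_prev - D) < config$convergence_tol) {
      converged <- TRUE
      D_prev <- D
      break
    }
    D_prev <- D
  }
  # final correspondences under the final transform, so that every paired
  # distance respects the epsilon cutoff
  j <- nn_index(S, Tm)
  d2 <- rowSums((S - Tm[j, , drop = FALSE])^2)
  keep <- which(d2 <= config$epsilon^2)
  structure(list(transform = total,
                 correspondences = cbind(source = keep, target = j[keep]),
                 final_D = if (length(keep)) sum(d2[keep]) else Inf,
                 D_trace = D_trace, D_pre_trace = D_pre_trace,
                 iterations = iter, converged = converged,
                 non_overlapping = length(keep) == 0),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> %d iterations, |C| = %d, D = %s%s\n",
              x$iterations, nrow(x$correspondences),
              format(x$final_D, digits = 6),
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
glance.icp_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations,
                 n_correspondences = nrow(x$correspondences),
                 final_D = x$final_D, converged = x$converged,
                 non_overlapping = x$non_overlapping)
}

scale_features <- function(features, stats_ref) {
  sweep(sweep(features, 2, stats_ref$mean), 2, stats_ref$sd, "/")
}

feature_stats <- function(feature_list) {
  all <- do.call(rbind, feature_list)
  sd0 <- apply(all, 2, stats::sd)
  list(mean = colMeans(all), sd = ifelse(sd0 < 1e-12, 1, sd0))
}

#' Six-dimensional patch distance D2
#'
#' Over the final ICP correspondence set, each point becomes the 6-vector
#' (x, y, z, electrostatics, hbond, hydrophobicity); D2 is the summed
#' squared 6D distance divided by the number of correspondences, so poorly
#' overlapping pairs (small corresponding sets) are penalised. Returns the
#' `Inf` sentinel when the ICP found no correspondences.
#'
#' @param source,target The [feature_cloud()] pair given to [icp_align()].
#' @param icp The [icp_align()] result for that pair.
#' @param config An [icp_config()]; `feature_scaling = "zscore"` scales
#'   feature columns by `stats_ref` (or statistics over the two clouds).
#' @param stats_ref Optional list (`mean`, `sd` per feature column)
#'   computed across the whole dataset with which to scale features.
#' @return Non-negative numeric score; lower means more similar.
#' @export
d2_score <- function(source, target, icp, config = icp_config(),
                     stats_ref = NULL) {
  if (nrow(icp$correspondences) == 0) return(Inf)
  if (ncol(source$features) != 3 || ncol(target$features) != 3) {
    stop("feature dimensionality must be 3")
  }
  fs <- source$features
  ft <- target$features
  if (config$feature_scaling == "zscore") {
    if (is.null(stats_ref)) stats_ref <- feature_stats(list(fs, ft))
    fs <- scale_features(fs, stats_ref)
    ft <- scale_features(ft, stats_ref)
  }
  Sp <- apply_transform(icp$transform, source$points)
  i <- icp$correspondences[, 1]
  j <- icp$correspondences[, 2]
  S6 <- cbind(Sp[i, , drop = FALSE], fs[i, , drop = FALSE])
  T6 <- cbind(target$points[j, , drop = FALSE], ft[j, , drop = FALSE])
  sum((S6 - T6)^2) / nrow(icp$correspondences)
}

#' Pairwise structural similarity matrix
#'
#' Runs ICP + D2 between every ordered pair of patch clouds and symmetrises
#' (mean of the two directions). The diagonal is 0. Non-overlapping pairs
#' (Inf sentinel) are replaced by 10 times the largest finite off-diagonal
#' cell so that one bad pair cannot poison fusion.
#'
#' @param clouds List of [feature_cloud()] objects (>= 2) in a common
#'   frame; names or cloud ids provide the matrix ids.
#' @param config An [icp_config()].
#' @return A [pepsim_matrix()] with component `"structural"`, orientation
#'   `"distance"`.
#' @export
structural_matrix <- function(clouds, config = icp_config()) {
  if (length(clouds) < 2) stop("need >= 2 clouds")
  ids <- names(clouds) %||% vapply(clouds, function(cl) cl$id, character(1))
  small <- vapply(clouds, function(cl) nrow(cl$points) < 4, logical(1))
  if (any(small)) {
    stop("clouds with < 4 points: ", paste(ids[small], collapse = ", "))
  }
  stats_ref <- if (config$feature_scaling == "zscore") {
    feature_stats(lapply(clouds, function(cl) cl$features))
  } else {
    NULL
  }
  n <- length(clouds)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- d2_score(clouds[[i]], clouds[[j]],
                      icp_align(clouds[[i]], clouds[[j]], config),
                      config, stats_ref)
      dji <- d2_score(clouds[[j]], clouds[[i]],
                      icp_align(clouds[[j]], clouds[[i]], config),
                      config, stats_ref)
      m[i, j] <- m[j, i] <- mean(c(dij, dji))
    }
  }
  if (any(!is.finite(m))) {
    finite_max <- max(m[is.finite(m)], 0)
    m[!is.finite(m)] <- if (finite_max > 0) finite_max * 10 else 1
  }
  pepsim_matrix(m, component = "structural", orientation = "distance")
}
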