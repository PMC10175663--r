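# Annotated surface point clouds: the objects aligned and scored by ICP.

#' Feature point cloud
#'
#' A set of surface points, each carrying 3 spatial coordinates (Angstrom)
#' and 3 biochemical features (electrostatic potential in kT/e,
#' hydrogen-bond potential in \[-1, 1\], Kyte-Doolittle hydrophobicity).
#'
#' @param points N x 3 numeric matrix of coordinates.
#' @param features N x 3 numeric matrix with columns `elec`, `hbond`,
#'   `hphob`.
#' @param id Identifier of the source peptide/complex.
#' @return An object of class `feature_cloud`.
#' @export
feature_cloud <- function(points, features, id = "cloud") {
  points <- as.matrix(points)
  features <- as.matrix(features)
  stopifnot(ncol(points) == 3, ncol(features) == 3,
            nrow(points) == nrow(features))
  if (!all(is.finite(features))) stop("features must be finite")
  if (any(features[, 2] < -1 - 1e-9) || any(features[, 2] > 1 + 1e-9)) {
    stop("hbond feature column must lie within [-1, 1]")
  }
  colnames(points) <- c("x", "y", "z")
  colnames(features) <- c("elec", "hbond", "hphob")
  structure(list(points = points, features = features, id = id),
            class = "feature_cloud")
}

#' @export
print.feature_cloud <- function(x, ...) {
  cat(sprintf("<feature_cloud> %s: %d points\n", x$id, nrow(x$points)))
  invisible(x)
}

#' @export
tidy.feature_cloud <- function(x, ...) {
  tibble::as_tibble(cbind(as.data.frame(x$points), as.data.frame(x$features)))
}

#' Write a feature cloud as CSV
#'
#' Columns `x`, `y`, `z`, `elec`, `hbond`, `hphob`.
#'
#' @param cloud A [feature_cloud()].
#' @param path Output CSV path.
#' @export
write_feature_cloud <- function(cloud, path) {
  utils::write.csv(tidy.feature_cloud(cloud), path, row.names = FALSE)
  invisible(path)
}

transform_cloud <- function(cloud, transform) {
  feature_cloud(apply_transform(transform, cloud$points), cloud$features,
                cloud$id)
}
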