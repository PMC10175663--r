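# Rigid-body geometry: nearest neighbours, Kabsch superposition, transforms.

#' Rigid transform
#'
#' A proper rigid-body transform `y = R x + t` with rotation `R` (3 x 3,
#' det +1) and translation `t` (length-3, Angstrom).
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation Numeric length-3 vector.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> angle", format(rotation_angle(x$rotation), digits = 4),
      "rad, |t| =", format(sqrt(sum(x$translation^2)), digits = 4), "A\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points N x 3 numeric matrix of coordinates.
#' @return N x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  points <- as.matrix(points)
  out <- sweep(points %*% t(transform$rotation), 2, -transform$translation)
  dimnames(out) <- dimnames(points)
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -t(transform$rotation) %*% transform$translation)
}

#' @rdname apply_transform
#' @param a,b Transforms; the composition applies `b` first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrix about an axis
#'
#' @param axis Length-3 axis (need not be unit).
#' @param angle Rotation angle in radians.
#' @return 3 x 3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' @rdname rotation_about_axis
#' @param rotation A 3 x 3 rotation matrix.
#' @export
rotation_angle <- function(rotation) {
  acos(min(1, max(-1, (sum(diag(rotation)) - 1) / 2)))
}

# Index of the nearest reference row for each query row. Chunked
# brute-force with deterministic tie-breaking (lowest index wins), so
# repeated runs give byte-identical results.
nn_index <- function(query, ref) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  if (nrow(ref) == 1L) return(rep(1L, nrow(query)))
  r2 <- rowSums(ref^2)
  out <- integer(nrow(query))
  chunk <- max(1L, floor(2e6 / nrow(ref)))
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    d2 <- outer(rep(1, length(idx)), r2) -
      2 * query[idx, , drop = FALSE] %*% t(ref)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rigid transform minimising the sum of squared
#' distances between paired points, mapping `moving` onto `fixed`.
#'
#' @param moving,fixed N x 3 matrices of paired coordinates (N >= 3 for a
#'   well-determined rotation; N >= 1 accepted, under-determined cases fall
#'   back to pure translation of the centroid).
#' @return A [rigid_transform()].
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cf - as.numeric(R %*% cm))
}
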