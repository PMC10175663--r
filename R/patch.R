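# TCR-facing surface patch: the circular neighbourhood of the surface
# point closest to the peptide's centre of mass, grown over the triangle
# edge graph.

#' Peptide centre of mass
#'
#' Mass-weighted centre of the peptide chain's heavy atoms (hydrogens
#' excluded, robust to protonation differences between modelling tools).
#'
#' @param complex A [phla_complex()].
#' @return Numeric length-3 vector (Angstrom).
#' @export
peptide_center_of_mass <- function(complex) {
  a <- complex$atoms
  a <- a[a$chain_id == complex$peptide_chain & a$element != "H", ,
         drop = FALSE]
  if (nrow(a) == 0) stop("peptide chain has no heavy atoms")
  m <- unname(ELEMENT_MASS[a$element])
  m[is.na(m)] <- 12
  colSums(as.matrix(a[, c("x", "y", "z")]) * m) / sum(m)
}

#' Extract the TCR-facing surface patch
#'
#' Finds the mesh vertex closest to the peptide's centre of mass (lowest
#' index on ties) and selects every vertex within `max_edges` hops of it
#' over the triangle edge graph (breadth-first). The selected vertices and
#' their features become an annotated point cloud.
#'
#' @param mesh A [surface_mesh()], index-aligned with `features`.
#' @param features A [vertex_features()] for the same mesh.
#' @param complex The source [phla_complex()].
#' @param max_edges Neighbourhood radius in edge hops (default 16).
#' @return A [feature_cloud()] whose id is the complex id.
#' @export
extract_patch <- function(mesh, features, complex, max_edges = 16) {
  if (nrow(mesh$vertices) == 0) stop("mesh is empty")
  if (length(features$elec) != nrow(mesh$vertices)) {
    stop("mesh and features are not index-aligned")
  }
  com <- peptide_center_of_mass(complex)
  d2 <- rowSums(sweep(mesh$vertices, 2, com)^2)
  center <- which(d2 == min(d2))[1]
  sel <- bfs_neighborhood(mesh$faces, nrow(mesh$vertices), center, max_edges)
  if (length(sel) < 4) {
    stop("patch has ", length(sel), " vertices (< 4) at max_edges = ",
         max_edges)
  }
  feature_cloud(mesh$vertices[sel, , drop = FALSE],
                cbind(elec = features$elec[sel],
                      hbond = features$hbond[sel],
                      hphob = features$hphob[sel]),
                id = complex$id)
}

# Vertex indices within `radius` edge hops of `start` (frontier BFS on the
# undirected triangle edge graph), returned in increasing index order.
bfs_neighborhood <- function(faces, n_vertices, start, radius) {
  e <- mesh_edges(faces)
  adj <- vector("list", n_vertices)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  visited <- logical(n_vertices)
  visited[start] <- TRUE
  frontier <- start
  hops <- 0
  while (hops < radius && length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
    hops <- hops + 1
  }
  which(visited)
}
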