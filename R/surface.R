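# Molecular surface meshing. The internal backend builds a probe-inflated
# Gaussian-density isosurface extracted by marching tetrahedra (each grid
# cube split into 6 tetrahedra sharing the main diagonal, which makes the
# triangulation watertight); the external backend wraps the MSMS binary.

#' Triangulated molecular surface mesh
#'
#' @param vertices M x 3 numeric matrix (Angstrom).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param vertex_normals M x 3 matrix of outward unit normals.
#' @param provenance Backend tag (`"internal"` or `"msms"`).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, vertex_normals, provenance) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  nrm <- as.matrix(vertex_normals)
  len <- sqrt(rowSums(nrm^2))
  if (any(abs(len - 1) > 1e-6)) {
    nrm <- nrm / pmax(len, 1e-12)
  }
  structure(list(vertices = vertices, faces = faces, vertex_normals = nrm,
                 provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$faces), x$provenance))
  invisible(x)
}

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Mesh topology helpers
#'
#' `euler_characteristic()` returns V - E + F (2 for a topological
#' sphere); `mesh_component_count()` the number of edge-connected
#' components.
#'
#' @param mesh A [surface_mesh()].
#' @return An integer.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh$faces)) + nrow(mesh$faces)
}

#' @rdname euler_characteristic
#' @export
mesh_component_count <- function(mesh) {
  g <- igraph::graph_from_edgelist(mesh_edges(mesh$faces), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::components(g)$no
}

keep_largest_component <- function(mesh) {
  g <- igraph::graph_from_edgelist(mesh_edges(mesh$faces), directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no <= 1) return(mesh)
  keep <- which(comp$membership == which.max(comp$csize))
  remap <- match(seq_len(nrow(mesh$vertices)), keep)
  f <- matrix(remap[mesh$faces], ncol = 3)
  f <- f[stats::complete.cases(f), , drop = FALSE]
  surface_mesh(mesh$vertices[keep, , drop = FALSE], f,
               mesh$vertex_normals[keep, , drop = FALSE], mesh$provenance)
}

# Marching-tetrahedra case table: for each of the 14 non-trivial sign
# patterns of a tetrahedron's 4 corners, the triangles to emit, as triples
# of edges (each edge a pair of corner slots 1..4).
mt_case_table <- function() {
  tbl <- vector("list", 15)
  for (case_id in 1:14) {
    inside <- which(bitwAnd(case_id, c(1L, 2L, 4L, 8L)) > 0)
    outside <- setdiff(1:4, inside)
    tris <- list()
    if (length(inside) %in% c(1, 3)) {
      c0 <- if (length(inside) == 1) inside else outside
      oth <- setdiff(1:4, c0)
      tris[[1]] <- rbind(c(c0, oth[1]), c(c0, oth[2]), c(c0, oth[3]))
    } else {
      a <- inside[1]; b <- inside[2]; cc <- outside[1]; d <- outside[2]
      e1 <- c(a, cc); e2 <- c(a, d); e3 <- c(b, cc); e4 <- c(b, d)
      tris[[1]] <- rbind(e1, e2, e4)
      tris[[2]] <- rbind(e1, e4, e3)
    }
    tbl[[case_id]] <- tris
  }
  tbl
}

MT_CASES <- mt_case_table()
# 6-tetrahedra cube decomposition around the 0-7 diagonal; corner ids 0..7
# encode (x, y, z) offsets as bits 1, 2, 4.
MT_TETS <- rbind(c(0, 5, 1, 7), c(0, 1, 3, 7), c(0, 3, 2, 7),
                 c(0, 2, 6, 7), c(0, 6, 4, 7), c(0, 4, 5, 7))

marching_tets_impl <- function(field, xs, ys, zs, iso) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nxy <- nx * ny
  inside <- field > iso
  corner_off <- c(0L, 1L, nx, nx + 1L, nxy, nxy + 1L, nxy + nx, nxy + nx + 1L)
  ci <- rep(seq_len(nx - 1), times = (ny - 1) * (nz - 1))
  cj <- rep(rep(seq_len(ny - 1), each = nx - 1), times = nz - 1)
  ck <- rep(seq_len(nz - 1), each = (nx - 1) * (ny - 1))
  c0 <- ci + (cj - 1L) * nx + (ck - 1L) * nxy
  scube <- integer(length(c0))
  for (o in corner_off) scube <- scube + inside[c0 + o]
  active <- c0[scube > 0 & scube < 8]
  if (length(active) == 0) stop("isosurface is empty at this grid")
  tri_g1 <- list(); tri_g2 <- list(); nblock <- 0
  for (tet in seq_len(nrow(MT_TETS))) {
    gidx <- cbind(active + corner_off[MT_TETS[tet, 1] + 1L],
                  active + corner_off[MT_TETS[tet, 2] + 1L],
                  active + corner_off[MT_TETS[tet, 3] + 1L],
                  active + corner_off[MT_TETS[tet, 4] + 1L])
    ins <- matrix(inside[gidx], ncol = 4)
    case_id <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    for (cid in 1:14) {
      rows <- which(case_id == cid)
      if (length(rows) == 0) next
      for (tri in MT_CASES[[cid]]) {
        nblock <- nblock + 1
        # rows x 3 edge endpoints, triangle-major after rbind of columns
        tri_g1[[nblock]] <- cbind(gidx[rows, tri[1, 1]],
                                  gidx[rows, tri[2, 1]],
                                  gidx[rows, tri[3, 1]])
        tri_g2[[nblock]] <- cbind(gidx[rows, tri[1, 2]],
                                  gidx[rows, tri[2, 2]],
                                  gidx[rows, tri[3, 2]])
      }
    }
  }
  G1 <- do.call(rbind, tri_g1)  # ntri x 3 grid endpoint 1
  G2 <- do.call(rbind, tri_g2)
  a <- pmin(G1, G2); b <- pmax(G1, G2)
  key <- as.numeric(a) * (nxy * nz + 1) + as.numeric(b)
  ukey <- unique(key)
  vid <- match(key, ukey)
  faces <- matrix(vid, ncol = 3)
  # interpolate unique edge vertices
  first <- match(ukey, key)
  ga <- as.numeric(a)[first]; gb <- as.numeric(b)[first]
  coord_of <- function(g) {
    g0 <- g - 1
    cbind(xs[g0 %% nx + 1], ys[(g0 %/% nx) %% ny + 1], zs[g0 %/% nxy + 1])
  }
  pa <- coord_of(ga); pb <- coord_of(gb)
  t <- (iso - field[ga]) / (field[gb] - field[ga])
  t[!is.finite(t)] <- 0.5
  t <- pmin(1, pmax(0, t))
  verts <- pa + t * (pb - pa)
  # degenerate faces (repeated vertex) can arise when an interpolated vertex
  # falls exactly on a grid point; drop them
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  list(vertices = verts, faces = faces[ok, , drop = FALSE])
}

# Trilinear interpolation of the field's central-difference gradient,
# used for outward normals (density decreases outward).
grid_gradient_at <- function(field, xs, ys, zs, pts) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nxy <- nx * ny
  f <- array(field, dim = c(nx, ny, nz))
  hx <- xs[2] - xs[1]; hy <- ys[2] - ys[1]; hz <- zs[2] - zs[1]
  gx <- (f[c(2:nx, nx), , ] - f[c(1, 1:(nx - 1)), , ]) / (2 * hx)
  gy <- (f[, c(2:ny, ny), ] - f[, c(1, 1:(ny - 1)), ]) / (2 * hy)
  gz <- (f[, , c(2:nz, nz)] - f[, , c(1, 1:(nz - 1))]) / (2 * hz)
  ix <- pmin(pmax(findInterval(pts[, 1], xs), 1), nx - 1)
  iy <- pmin(pmax(findInterval(pts[, 2], ys), 1), ny - 1)
  iz <- pmin(pmax(findInterval(pts[, 3], zs), 1), nz - 1)
  tx <- (pts[, 1] - xs[ix]) / hx
  ty <- (pts[, 2] - ys[iy]) / hy
  tz <- (pts[, 3] - zs[iz]) / hz
  interp <- function(g) {
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
        (if (dz) tz else 1 - tz)
      acc <- acc + w * g[cbind(ix + dx, iy + dy, iz + dz)]
    }
    acc
  }
  cbind(interp(gx), interp(gy), interp(gz))
}

#' Build a molecular surface mesh
#'
#' Computes a closed triangulated probe-rolled (solvent-excluded style)
#' molecular surface. The internal backend evaluates a Gaussian atom
#' density with probe-inflated van der Waals radii on a regular grid and
#' extracts the unit isosurface by marching tetrahedra; the external
#' backend shells out to the MSMS binary with the given density and probe
#' radius and parses its vertex/face files.
#'
#' @param complex A [phla_complex()] with at least one atom.
#' @param backend `"internal"` or `"external"` (MSMS).
#' @param probe_radius Probe sphere radius in Angstrom.
#' @param density MSMS vertex density (external backend only).
#' @param grid_spacing Grid step in Angstrom for the internal backend.
#' @param msms_bin Path to the MSMS executable; defaults to `PEPSIM_MSMS`
#'   or `msms` on the PATH.
#' @param keep_largest Drop interior cavity components, keeping the largest
#'   edge-connected surface (default TRUE).
#' @return A [surface_mesh()].
#' @export
build_surface_mesh <- function(complex, backend = c("internal", "external"),
                               probe_radius = 1.5, density = 3.0,
                               grid_spacing = 0.8, msms_bin = NULL,
                               keep_largest = TRUE) {
  backend <- match.arg(backend)
  atoms <- complex$atoms[complex$atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0) stop("complex has no heavy atoms")
  if (backend == "external") {
    return(msms_surface(atoms, probe_radius, density, msms_bin))
  }
  centers <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- unname(ELEMENT_VDW[atoms$element]) + probe_radius
  radii[is.na(radii)] <- 1.7 + probe_radius
  sharp <- 2.3
  cutoff <- radii * sqrt(1 + 6 / sharp)
  margin <- max(cutoff) + 2 * grid_spacing
  lo <- apply(centers, 2, min) - margin
  hi <- apply(centers, 2, max) + margin
  xs <- seq(lo[1], hi[1], by = grid_spacing)
  ys <- seq(lo[2], hi[2], by = grid_spacing)
  zs <- seq(lo[3], hi[3], by = grid_spacing)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  field <- numeric(nx * ny * nz)
  for (a in seq_len(nrow(centers))) {
    ix <- which(abs(xs - centers[a, 1]) <= cutoff[a])
    iy <- which(abs(ys - centers[a, 2]) <= cutoff[a])
    iz <- which(abs(zs - centers[a, 3]) <= cutoff[a])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - centers[a, 1])^2
    dy2 <- (ys[iy] - centers[a, 2])^2
    dz2 <- (zs[iz] - centers[a, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    idx <- outer(outer(ix, (iy - 1L) * nx, "+"), (iz - 1L) * (nx * ny), "+")
    field[idx] <- field[idx] + exp(sharp * (1 - d2 / radii[a]^2))
  }
  mt <- marching_tets_impl(field, xs, ys, zs, iso = 1)
  grad <- grid_gradient_at(field, xs, ys, zs, mt$vertices)
  nrm <- -grad / pmax(sqrt(rowSums(grad^2)), 1e-12)
  mesh <- surface_mesh(mt$vertices, mt$faces, nrm, provenance = "internal")
  if (keep_largest) mesh <- keep_largest_component(mesh)
  mesh
}

msms_surface <- function(atoms, probe_radius, density, msms_bin) {
  bin <- msms_bin %||% Sys.getenv("PEPSIM_MSMS", unset = "")
  if (bin == "") bin <- Sys.which("msms")
  if (bin == "" || !file.exists(bin)) {
    stop("MSMS binary not found (set msms_bin, PEPSIM_MSMS, or PATH); ",
         "use backend = 'internal' for the built-in isosurface")
  }
  radii <- unname(ELEMENT_VDW[atoms$element])
  radii[is.na(radii)] <- 1.7
  stem <- tempfile("msms")
  utils::write.table(cbind(atoms$x, atoms$y, atoms$z, radii),
                     paste0(stem, ".xyzr"),
                     row.names = FALSE, col.names = FALSE)
  status <- system2(bin, c("-if", paste0(stem, ".xyzr"), "-of", stem,
                           "-density", density,
                           "-probe_radius", probe_radius),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(paste0(stem, ".vert"))) {
    stop("MSMS run failed with status ", status)
  }
  vert <- utils::read.table(paste0(stem, ".vert"), skip = 3)
  face <- utils::read.table(paste0(stem, ".face"), skip = 3)
  surface_mesh(as.matrix(vert[, 1:3]), as.matrix(face[, 1:3]),
               as.matrix(vert[, 4:6]), provenance = "msms")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Downsample a mesh by vertex clustering
#'
#' Clusters vertices on a cubic grid of the requested resolution, replaces
#' each cluster by its centroid, remaps faces, and drops degenerate and
#' duplicate faces. Vertex count never increases and connectivity is
#' preserved (clustering only merges).
#'
#' @param mesh A [surface_mesh()].
#' @param resolution Target resolution in Angstrom (> 0).
#' @return A [surface_mesh()].
#' @export
downsample_mesh <- function(mesh, resolution = 1.0) {
  if (resolution <= 0) stop("resolution must be > 0")
  v <- mesh$vertices
  # grid anchored at absolute coordinates: cluster centroids stay inside
  # their (convex) cells, so the operation is idempotent
  cell <- floor(v / resolution)
  cell <- sweep(cell, 2, apply(cell, 2, min))
  key <- cell[, 1] * 1e10 + cell[, 2] * 1e5 + cell[, 3]
  ukey <- unique(key)
  cl <- match(key, ukey)
  nv <- length(ukey)
  newv <- matrix(0, nv, 3)
  for (d in 1:3) newv[, d] <- tapply(v[, d], cl, mean)[as.character(seq_len(nv))]
  newn <- matrix(0, nv, 3)
  for (d in 1:3) {
    newn[, d] <- tapply(mesh$vertex_normals[, d], cl,
                        mean)[as.character(seq_len(nv))]
  }
  f <- matrix(cl[mesh$faces], ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[ok, , drop = FALSE]
  fs <- t(apply(f, 1, sort))
  f <- f[!duplicated(fs), , drop = FALSE]
  used <- sort(unique(as.integer(f)))
  remap <- match(seq_len(nv), used)
  surface_mesh(newv[used, , drop = FALSE],
               matrix(remap[f], ncol = 3),
               newn[used, , drop = FALSE],
               provenance = mesh$provenance)
}

#' Export a mesh as OFF
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
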