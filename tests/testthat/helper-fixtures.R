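# Shared fixtures, built once per test run. Heavier objects (meshed
# complexes) are cached so multiple test files can reuse them.

# bare-bones complex builder for small feature/patch fixtures: a short
# chain of residues at given CA positions with one CA atom each, plus
# optional named extra atoms
toy_complex <- function(residues, ca_positions, extra = NULL,
                        id = "toy", chain = "C") {
  atoms <- tibble::tibble(
    element = "C", name = "CA",
    residue_name = unname(pepsim:::AA_THREE[residues]),
    residue_index = seq_along(residues), chain_id = chain,
    x = ca_positions[, 1], y = ca_positions[, 2], z = ca_positions[, 3],
    occupancy = 1, bfactor = 0
  )
  if (!is.null(extra)) atoms <- dplyr::bind_rows(atoms, extra)
  structure(list(id = id, atoms = atoms, peptide_chain = chain,
                 hla_chain = "A", peptide_sequence =
                   paste(residues, collapse = "")),
            class = "phla_complex")
}

# a 6 x 6 planar grid mesh (two triangles per cell); vertex (i, j) has
# index (j - 1) * 6 + i and sits at (i, j, 0)
grid_mesh_6x6 <- function() {
  n <- 6
  verts <- cbind(rep(1:n, n), rep(1:n, each = n), 0)
  faces <- NULL
  for (j in 1:(n - 1)) {
    for (i in 1:(n - 1)) {
      v <- (j - 1) * n + i
      faces <- rbind(faces, c(v, v + 1, v + n), c(v + 1, v + n + 1, v + n))
    }
  }
  surface_mesh(verts, faces, matrix(rep(c(0, 0, 1), each = n * n), ncol = 3),
               provenance = "internal")
}

uniform_features <- function(n, elec = 0, hbond = 0, hphob = 0) {
  vertex_features(rep(elec, n), rep(hbond, n), rep(hphob, n))
}

cached <- local({
  env <- new.env()
  function(name, expr) {
    if (!exists(name, envir = env)) assign(name, force(expr), envir = env)
    get(name, envir = env)
  }
})

# meshed + annotated synthetic complex shared across surface/patch tests
fixture_meshed_complex <- function() {
  cached("meshed", {
    cpx <- make_synthetic_phla("EVDPIGHLY", seed = 1)
    mesh <- downsample_mesh(build_surface_mesh(cpx, grid_spacing = 1.0), 1.0)
    feats <- annotate_features(mesh, cpx)
    list(cpx = cpx, mesh = mesh, feats = feats)
  })
}

# independent brute-force helpers (test oracles)
brute_nearest <- function(query, ref) {
  apply(query, 1, function(p) {
    which.min(colSums((t(ref) - p)^2))
  })
}

brute_knn_loo <- function(m, labels, k) {
  n <- nrow(m)
  vapply(seq_len(n), function(i) {
    d <- m[i, -i]
    lab <- labels[-i]
    ord <- order(d, names(d))
    nb <- lab[ord[seq_len(k)]]
    if (sum(nb) * 2 == k) nb[1] else sum(nb) * 2 > k
  }, logical(1))
}

random_fused_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(sprintf("p%02d", 1:n), sprintf("p%02d", 1:n))
  pepsim_matrix(m, component = "fused", orientation = "distance")
}
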