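# Synthetic fixtures: toy peptide-HLA structures (a rigid groove scaffold
# plus a peptide laid in extended conformation) and annotated point-cloud
# pairs with known rigid transforms. These stand in for docked/modelled
# complexes so every downstream step is testable without external data.

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Canonical side-chain heavy atom names beyond CB, in build order.
SIDECHAIN_ATOMS <- list(
  A = character(), G = character(), C = "SG", S = "OG", T = c("OG1", "CG2"),
  V = c("CG1", "CG2"), P = c("CG", "CD"), I = c("CG1", "CG2", "CD1"),
  L = c("CG", "CD1", "CD2"), N = c("CG", "OD1", "ND2"),
  D = c("CG", "OD1", "OD2"), M = c("CG", "SD", "CE"),
  Q = c("CG", "CD", "OE1", "NE2"), E = c("CG", "CD", "OE1", "OE2"),
  K = c("CG", "CD", "CE", "NZ"), H = c("CG", "ND1", "CD2", "CE1", "NE2"),
  R = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
  F = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  Y = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  W = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

scaffold_atoms <- function() {
  rows <- list()
  add_res <- function(cx, cy, cz, cb_dir) {
    list(N = c(cx - 1.2, cy + 0.4, cz),
         CA = c(cx, cy, cz),
         C = c(cx + 1.2, cy + 0.4, cz),
         O = c(cx + 1.2, cy + 1.4, cz + 0.5),
         CB = c(cx, cy, cz) + 1.5 * cb_dir)
  }
  # groove floor: 4 strands of 20 residues at z = 0, CB pointing down
  for (yi in c(-7.2, -2.4, 2.4, 7.2)) {
    for (xi in 0:19) {
      rows[[length(rows) + 1]] <- add_res(xi * 3.5, yi, 0, c(0, 0, -1))
    }
  }
  # groove walls: 2 stacked strands of 20 residues each side, CB inward
  for (side in c(-1, 1)) {
    for (zi in c(4, 8)) {
      for (xi in 0:19) {
        rows[[length(rows) + 1]] <-
          add_res(xi * 3.5, side * 9.5, zi, c(0, -side, 0))
      }
    }
  }
  n <- length(rows)
  atom_names <- c("N", "CA", "C", "O", "CB")
  coords <- do.call(rbind, lapply(rows, function(r) do.call(rbind, r)))
  tibble::tibble(
    element = element_of_atom(rep(atom_names, n)),
    name = rep(atom_names, n),
    residue_name = "ALA",
    residue_index = rep(seq_len(n), each = 5L),
    chain_id = "A",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, bfactor = 0
  )
}

peptide_atoms <- function(letters1, seed) {
  L <- length(letters1)
  x0 <- (19 * 3.5) / 2 - (L - 1) * 3.2 / 2
  rows <- list()
  with_local_seed(seed + 1000L, {
    for (i in seq_len(L)) {
      aa <- letters1[i]
      ca <- c(x0 + (i - 1) * 3.2, 0.6 * (-1)^i, 5.5)
      at <- list(N = ca + c(-1.2, 0.3, 0), CA = ca, C = ca + c(1.2, 0.3, 0),
                 O = ca + c(1.2, 1.3, 0.4))
      if (aa != "G") at$CB <- ca + c(0, 0.4 * (-1)^i, 1.4)
      extra <- SIDECHAIN_ATOMS[[aa]]
      for (k in seq_along(extra)) {
        jitter <- stats::runif(2, -0.35, 0.35)
        at[[extra[k]]] <- at$CB + c(jitter[1], jitter[2], 1.2 * k)
      }
      coords <- do.call(rbind, at)
      rows[[i]] <- tibble::tibble(
        element = element_of_atom(names(at)),
        name = names(at),
        residue_name = unname(AA_THREE[aa]),
        residue_index = i,
        chain_id = "C",
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        occupancy = 1, bfactor = 0
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' Generate a synthetic peptide-HLA complex
#'
#' Builds a toy pHLA structure: a rigid "groove" scaffold chain of 160
#' pseudo-residues (backbone + C-beta), identical across peptides and seeds
#' so that score differences between fixtures are attributable to the
#' peptide, plus the requested peptide laid in extended conformation inside
#' the groove with side-chain pseudo-atoms named and sized per residue. The
#' seed perturbs only peptide side-chain placement. Deterministic for a
#' given (sequence, seed); round-trips through [parse_phla_pdb()].
#'
#' @param peptide_sequence One-letter sequence of length 8-11, standard
#'   residues only.
#' @param seed Integer seed for side-chain jitter.
#' @param file Optional path; when given, the complex is also written as a
#'   PDB file there.
#' @return A [phla_complex()] (invisibly carries `file` as attribute
#'   `"path"` when written).
#' @export
#' @examples
#' cpx <- make_synthetic_phla("EVDPIGHLY", seed = 1)
#' cpx$peptide_sequence
make_synthetic_phla <- function(peptide_sequence, seed = 1L, file = NULL) {
  L <- nchar(peptide_sequence)
  if (L < 8 || L > 11) {
    stop("peptide_sequence must be 8-11 residues, got ", L)
  }
  letters1 <- check_standard_residues(peptide_sequence)
  atoms <- dplyr::bind_rows(scaffold_atoms(), peptide_atoms(letters1, seed))
  cpx <- phla_complex(id = peptide_sequence, atoms = atoms,
                      peptide_chain = "C", hla_chain = "A",
                      peptide_sequence = peptide_sequence)
  if (!is.null(file)) {
    write_phla_pdb(cpx, file)
    attr(cpx, "path") <- file
  }
  cpx
}

#' Write a complex as a PDB file
#'
#' @param complex A [phla_complex()].
#' @param file Output path.
#' @export
write_phla_pdb <- function(complex, file) {
  a <- complex$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$residue_index, resid = a$residue_name,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain_id, o = a$occupancy, b = a$bfactor,
                   elesy = a$element)
  invisible(file)
}

#' Generate a synthetic annotated point-cloud pair
#'
#' Draws a base cloud of points with smoothly varying biochemical features,
#' then produces a second cloud by applying a known rigid transform (the
#' stated rotation about the cloud centroid plus the stated translation)
#' with optional Gaussian noise added to the features only. The true
#' transform maps the first cloud onto the second, so registration can be
#' checked against ground truth.
#'
#' @param n_points Number of points (>= 4).
#' @param rotation_angle Rotation angle in degrees.
#' @param translation Length-3 translation vector (Angstrom).
#' @param feature_noise_sd Standard deviation of Gaussian feature noise on
#'   the second cloud.
#' @param seed Integer seed.
#' @return A list with elements `source` and `target` ([feature_cloud()]s)
#'   and `transform` (the true [rigid_transform()] with
#'   `target = transform(source)` up to feature noise).
#' @export
make_synthetic_cloud_pair <- function(n_points, rotation_angle = 0,
                                      translation = c(0, 0, 0),
                                      feature_noise_sd = 0, seed = 1L) {
  if (n_points < 4) {
    stop("n_points must be >= 4 (rigid registration is underdetermined)")
  }
  with_local_seed(seed, {
    pts <- matrix(stats::runif(3 * n_points, -5, 5), ncol = 3)
    feats <- cbind(elec = 4 * sin(pts[, 1] / 2) + pts[, 2] / 3,
                   hbond = pmax(-1, pmin(1, sin(pts[, 3]))),
                   hphob = unname(KYTE_DOOLITTLE[
                     sample(AA_STANDARD, n_points, replace = TRUE)]))
    axis <- stats::rnorm(3)
    R <- rotation_about_axis(axis, rotation_angle * pi / 180)
    ctr <- colMeans(pts)
    tf <- rigid_transform(R, ctr - as.numeric(R %*% ctr) + translation)
    feats2 <- feats
    if (feature_noise_sd > 0) {
      feats2 <- feats + matrix(stats::rnorm(length(feats), 0, feature_noise_sd),
                               ncol = 3)
      feats2[, 2] <- pmax(-1, pmin(1, feats2[, 2]))
    }
    list(source = feature_cloud(pts, feats, id = "source"),
         target = feature_cloud(apply_transform(tf, pts), feats2,
                                id = "target"),
         transform = tf)
  })
}

#' Generate a synthetic labelled peptide set
#'
#' Produces a small dataset with the structure of a cross-reactivity study:
#' a family of near-duplicate peptides (single conservative substitutions of
#' a base sequence, standing in for peptides recognised by one T-cell
#' clone) and a set of unrelated decoys, all as synthetic complexes sharing
#' one scaffold.
#'
#' @param n_positive,n_negative Family and decoy sizes.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, PDB files and a
#'   `manifest.csv` are written there.
#' @return A tibble with columns `peptide`, `label`, `complex`
#'   (list-column of [phla_complex()]), and `path` when written.
#' @export
make_synthetic_dataset <- function(n_positive = 5, n_negative = 5,
                                   seed = 1L, dir = NULL) {
  base <- "EVDPIGHLY"
  # conservative single substitutions for the positive family
  conservative <- list(E = "D", V = "I", D = "E", P = "A", I = "L",
                       G = "A", H = "Q", L = "M", Y = "F")
  with_local_seed(seed, {
    pos <- base
    while (length(pos) < n_positive) {
      p <- sample(nchar(base), 1)
      aa <- substr(base, p, p)
      s <- base
      substr(s, p, p) <- conservative[[aa]]
      pos <- unique(c(pos, s))
    }
    negs <- character(0)
    while (length(negs) < n_negative) {
      s <- paste(sample(AA_STANDARD, nchar(base), replace = TRUE),
                 collapse = "")
      if (!s %in% c(pos, negs)) negs <- c(negs, s)
    }
    peptides <- c(pos, negs)
    labels <- rep(c(TRUE, FALSE), c(length(pos), length(negs)))
    seeds <- sample.int(10000, length(peptides))
    out <- tibble::tibble(peptide = peptides, label = labels)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      out$path <- file.path(dir, paste0(out$peptide, ".pdb"))
    }
    out$complex <- purrr::pmap(
      list(out$peptide, seeds, if (is.null(dir)) list(NULL) else out$path),
      function(p, s, f) make_synthetic_phla(p, seed = s, file = f))
    if (!is.null(dir)) {
      utils::write.csv(
        data.frame(path = basename(out$path), peptide = out$peptide,
                   label = out$label, response = ifelse(out$label, "high", "none")),
        file.path(dir, "manifest.csv"), row.names = FALSE)
    }
    out
  })
}
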