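# Per-vertex biochemical annotation of a surface mesh: Kyte-Doolittle
# hydrophobicity of the nearest residue, electrostatic potential (screened
# Coulomb with a fixed formal-charge scheme, or an externally computed APBS
# grid), and a simplified orientation-dependent hydrogen-bond potential.

#' Vertex features
#'
#' @param elec Electrostatic potential per vertex (kT/e, clipped to
#'   \[-30, 30\]).
#' @param hbond Hydrogen-bond potential per vertex in \[-1, 1\]
#'   (+1 donor-like, -1 acceptor-like).
#' @param hphob Kyte-Doolittle hydrophobicity of the owning residue.
#' @return An object of class `vertex_features` (list of the three numeric
#'   vectors).
#' @export
vertex_features <- function(elec, hbond, hphob) {
  stopifnot(length(elec) == length(hbond), length(hbond) == length(hphob))
  if (any(hbond < -1 - 1e-9 | hbond > 1 + 1e-9)) {
    stop("hbond potential must lie within [-1, 1]")
  }
  structure(list(elec = elec, hbond = pmin(1, pmax(-1, hbond)),
                 hphob = hphob),
            class = "vertex_features")
}

#' @export
print.vertex_features <- function(x, ...) {
  cat(sprintf("<vertex_features> %d vertices; elec [%.2f, %.2f] kT/e, hbond [%.2f, %.2f]\n",
              length(x$elec), min(x$elec), max(x$elec), min(x$hbond),
              max(x$hbond)))
  invisible(x)
}

# kT/e Coulomb prefactor at 298 K: e^2 / (4 pi eps0 * 1 Angstrom * kB T)
COULOMB_KT_E <- 560.7

residue_partial_charges <- function(atoms) {
  q <- numeric(nrow(atoms))
  key <- paste(atoms$chain_id, atoms$residue_index)
  for (res_key in unique(key)) {
    rows <- which(key == res_key)
    aa <- AA_ONE[atoms$residue_name[rows[1]]]
    if (is.na(aa) || !aa %in% names(RESIDUE_CHARGE)) next
    scheme <- RESIDUE_CHARGE[[aa]]
    hit <- rows[atoms$name[rows] %in% scheme$atoms]
    if (length(hit) == 0) {
      # fall back to the outermost side-chain heavy atom, else CA
      side <- rows[!atoms$name[rows] %in% c("N", "CA", "C", "O") &
                     atoms$element[rows] != "H"]
      hit <- if (length(side) > 0) side[length(side)] else
        rows[atoms$name[rows] == "CA"]
    }
    if (length(hit) > 0) q[hit] <- scheme$q / length(hit)
  }
  # termini: +1 on the first backbone N, -1 on the last backbone O/OXT of
  # each chain
  for (ch in unique(atoms$chain_id)) {
    rows <- which(atoms$chain_id == ch)
    first_res <- rows[atoms$residue_index[rows] == min(atoms$residue_index[rows])]
    last_res <- rows[atoms$residue_index[rows] == max(atoms$residue_index[rows])]
    nterm <- first_res[atoms$name[first_res] == "N"]
    if (length(nterm) > 0) q[nterm[1]] <- q[nterm[1]] + 1
    cterm <- last_res[atoms$name[last_res] %in% c("O", "OXT")]
    if (length(cterm) > 0) q[cterm] <- q[cterm] - 1 / length(cterm)
  }
  q
}

hbond_sites <- function(atoms) {
  aa <- AA_ONE[atoms$residue_name]
  nm <- atoms$name
  donor <- nm %in% HBOND_DONORS$all
  acceptor <- nm %in% HBOND_ACCEPTORS$all
  for (r in setdiff(names(HBOND_DONORS), "all")) {
    donor <- donor | (aa %in% r & nm %in% HBOND_DONORS[[r]])
  }
  for (r in setdiff(names(HBOND_ACCEPTORS), "all")) {
    acceptor <- acceptor | (aa %in% r & nm %in% HBOND_ACCEPTORS[[r]])
  }
  list(donor = which(donor & atoms$element != "H"),
       acceptor = which(acceptor & atoms$element != "H"))
}

# Outward axis of a polar group: from the residue's CA (or residue centroid)
# through the site atom.
site_axes <- function(atoms, sites) {
  key <- paste(atoms$chain_id, atoms$residue_index)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  axes <- matrix(0, length(sites), 3)
  for (i in seq_along(sites)) {
    s <- sites[i]
    rows <- which(key == key[s])
    ca <- rows[atoms$name[rows] == "CA"]
    origin <- if (length(ca) > 0) coords[ca[1], ] else colMeans(coords[rows, , drop = FALSE])
    ax <- coords[s, ] - origin
    n <- sqrt(sum(ax^2))
    axes[i, ] <- if (n > 1e-6) ax / n else c(0, 0, 1)
  }
  axes
}

# Signed, distance- and angle-attenuated potential from polar sites.
# Gaussian (sigma 1 A) about the ideal heavy-atom hydrogen-bond distance
# of 2.9 A, times the cosine of the deviation from the site's outward
# axis (floored at 0), zero beyond 3.5 A. The dominant contribution wins.
hbond_potential <- function(vertices, atoms) {
  sites <- hbond_sites(atoms)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  out <- numeric(nrow(vertices))
  best <- numeric(nrow(vertices))
  for (kind in c("donor", "acceptor")) {
    idx <- sites[[kind]]
    if (length(idx) == 0) next
    axes <- site_axes(atoms, idx)
    sgn <- if (kind == "donor") 1 else -1
    for (i in seq_along(idx)) {
      dvec <- sweep(vertices, 2, coords[idx[i], ])
      r <- sqrt(rowSums(dvec^2))
      near <- which(r <= 3.5 & r > 1e-9)
      if (length(near) == 0) next
      cosang <- pmax(0, (dvec[near, , drop = FALSE] %*% axes[i, ])[, 1] /
                          r[near])
      mag <- exp(-(r[near] - 2.9)^2 / 2) * cosang
      hit <- near[mag > best[near]]
      if (length(hit) > 0) {
        m <- mag[match(hit, near)]
        best[hit] <- m
        out[hit] <- sgn * m
      }
    }
  }
  pmin(1, pmax(-1, out))
}

#' Annotate mesh vertices with biochemical features
#'
#' Assigns to each mesh vertex (1) the Kyte-Doolittle hydrophobicity of the
#' residue owning the nearest heavy atom, (2) an electrostatic potential --
#' either a screened Coulomb sum over a fixed formal-charge scheme
#' (Asp/Glu -1, Lys/Arg +1, His +0.1, termini +/-1, distributed over the
#' charged-group heavy atoms; Debye screening length 8 Angstrom, protein
#' dielectric 4), or trilinear interpolation of an externally computed
#' APBS potential grid in OpenDX format -- clipped to \[-30, 30\] kT/e, and
#' (3) a simplified orientation-dependent hydrogen-bond potential in
#' \[-1, 1\] (positive near donors, negative near acceptors, attenuated by
#' distance and axis angle, zero beyond 3.5 Angstrom of any polar group).
#'
#' @param mesh A [surface_mesh()].
#' @param complex The [phla_complex()] the mesh was built from.
#' @param electrostatics_backend `"coulomb"` (built-in) or `"external"`
#'   (requires `apbs_grid`).
#' @param apbs_grid Path to an OpenDX potential grid for the external
#'   backend.
#' @param debye_length Screening length in Angstrom.
#' @param dielectric Relative dielectric constant for the Coulomb backend.
#' @return A [vertex_features()] aligned with the mesh vertices.
#' @export
annotate_features <- function(mesh, complex,
                              electrostatics_backend = c("coulomb", "external"),
                              apbs_grid = NULL, debye_length = 8,
                              dielectric = 4) {
  electrostatics_backend <- match.arg(electrostatics_backend)
  atoms <- complex$atoms[complex$atoms$element != "H", , drop = FALSE]
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  v <- mesh$vertices
  nearest <- nn_index(v, coords)
  aa <- AA_ONE[atoms$residue_name[nearest]]
  unknown <- is.na(aa)
  if (any(unknown)) {
    warning(sum(unknown), " vertices map to unknown residues; features set to 0")
  }
  hphob <- as.numeric(ifelse(unknown, 0, KYTE_DOOLITTLE[aa]))
  if (electrostatics_backend == "external") {
    if (is.null(apbs_grid)) {
      stop("external electrostatics backend needs an APBS OpenDX grid file")
    }
    elec <- interpolate_dx_grid(read_dx_grid(apbs_grid), v)
  } else {
    q <- residue_partial_charges(atoms)
    charged <- which(q != 0)
    elec <- numeric(nrow(v))
    for (i in charged) {
      r <- sqrt(rowSums(sweep(v, 2, coords[i, ])^2))
      elec <- elec + COULOMB_KT_E * q[i] * exp(-r / debye_length) /
        (dielectric * pmax(r, 0.5))
    }
  }
  elec <- pmin(30, pmax(-30, elec))
  # donor sites are the polar heavy atoms themselves (idealised-H stand-in)
  hb <- hbond_potential(v, complex$atoms)
  vertex_features(elec = elec, hbond = hb, hphob = hphob)
}

# Minimal OpenDX scalar-grid reader (the dialect APBS writes): counts from
# "object 1 class gridpositions counts nx ny nz", origin and three delta
# lines, then whitespace-separated values in z-fastest order.
read_dx_grid <- function(path) {
  lines <- readLines(path)
  counts <- as.integer(strsplit(trimws(sub(
    ".*counts", "", grep("gridpositions counts", lines, value = TRUE)[1])),
    "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub(
    "origin", "", grep("^origin", lines, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- t(vapply(grep("^delta", lines, value = TRUE)[1:3], function(l) {
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  data_start <- grep("class array", lines)[1] + 1
  data_end <- length(lines)
  att <- grep("^attribute|^object \"|^component", lines)
  att <- att[att > data_start]
  if (length(att) > 0) data_end <- min(att) - 1
  vals <- as.numeric(unlist(strsplit(trimws(lines[data_start:data_end]),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(counts)) {
    stop("DX grid has ", length(vals), " values, expected ", prod(counts))
  }
  list(counts = counts, origin = origin,
       spacing = c(deltas[1, 1], deltas[2, 2], deltas[3, 3]),
       # DX data order: z fastest -> store as [z, y, x] then use aperm
       values = aperm(array(vals, dim = rev(counts)), c(3, 2, 1)))
}

interpolate_dx_grid <- function(grid, pts) {
  nx <- grid$counts[1]; ny <- grid$counts[2]; nz <- grid$counts[3]
  gx <- (pts[, 1] - grid$origin[1]) / grid$spacing[1]
  gy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2]
  gz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3]
  ix <- pmin(pmax(floor(gx), 0), nx - 2); tx <- gx - ix
  iy <- pmin(pmax(floor(gy), 0), ny - 2); ty <- gy - iy
  iz <- pmin(pmax(floor(gz), 0), nz - 2); tz <- gz - iz
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  tz <- pmin(pmax(tz, 0), 1)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
      (if (dz) tz else 1 - tz)
    acc <- acc + w * grid$values[cbind(ix + dx + 1, iy + dy + 1, iz + dz + 1)]
  }
  acc
}
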