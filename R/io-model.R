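# Parsing peptide-HLA complexes from PDB files and resolving chain roles.
# bio3d does the PDB record parsing; this layer decides which chain is the
# bound peptide and which is the HLA heavy chain.

#' Peptide-HLA complex
#'
#' Container for the parsed atoms of one peptide-HLA class I structure with
#' chain roles resolved. Atoms are stored as a tibble (one row per atom)
#' with columns `element`, `name`, `residue_name`, `residue_index`,
#' `chain_id`, `x`, `y`, `z`, `occupancy`, `bfactor`.
#'
#' @param id Identifier (peptide sequence or file stem).
#' @param atoms Atom tibble as described above.
#' @param peptide_chain,hla_chain Single-character chain identifiers.
#' @param peptide_sequence One-letter peptide sequence, in residue-index
#'   order of the peptide chain.
#' @return An object of class `phla_complex`.
#' @export
phla_complex <- function(id, atoms, peptide_chain, hla_chain,
                         peptide_sequence) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "name", "residue_name", "residue_index",
                  "chain_id", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  x <- structure(list(id = id, atoms = atoms, peptide_chain = peptide_chain,
                      hla_chain = hla_chain,
                      peptide_sequence = peptide_sequence),
                 class = "phla_complex")
  np <- length(unique(atoms$residue_index[atoms$chain_id == peptide_chain]))
  if (np < 8 || np > 11) {
    stop(sprintf("peptide chain '%s' has %d residues; expected 8-11",
                 peptide_chain, np))
  }
  if (nchar(peptide_sequence) != np) {
    stop("peptide_sequence length does not match the peptide chain")
  }
  x
}

#' @export
print.phla_complex <- function(x, ...) {
  cat(sprintf("<phla_complex> %s: peptide %s (chain %s), HLA chain %s, %d atoms\n",
              x$id, x$peptide_sequence, x$peptide_chain, x$hla_chain,
              nrow(x$atoms)))
  invisible(x)
}

chain_residue_counts <- function(atoms) {
  tapply(atoms$residue_index, atoms$chain_id,
         function(r) length(unique(r)))
}

chain_sequence <- function(atoms, chain) {
  a <- atoms[atoms$chain_id == chain, ]
  a <- a[order(a$residue_index), ]
  res <- a$residue_name[!duplicated(a$residue_index)]
  one <- AA_ONE[res]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Parse a peptide-HLA PDB file
#'
#' Reads the ATOM records of a PDB file, resolves alternate locations to the
#' highest-occupancy copy, discards HETATM records, and assigns chain roles:
#' the peptide chain is the hint when given, otherwise the chain with 8-11
#' residues (shortest wins a tie, with a warning); the HLA chain is the
#' longest remaining chain. Hydrogens are retained when present.
#'
#' @param path Path to a PDB file with at least two chains.
#' @param peptide_chain_hint Optional chain identifier overriding peptide
#'   chain detection.
#' @param id Identifier for the complex; defaults to the file stem.
#' @return A [phla_complex()].
#' @export
parse_phla_pdb <- function(path, peptide_chain_hint = NULL, id = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) stop("no ATOM records in ", path)
  # altloc: keep the highest-occupancy copy of each (chain, resno, atom name)
  if (any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(a$chain, a$resno, a$elety)
    occ <- ifelse(is.na(a$o), 1, a$o)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
  }
  elem <- a$elesy
  bad <- is.na(elem) | trimws(elem) == ""
  elem[bad] <- element_of_atom(a$elety[bad])
  atoms <- tibble::tibble(
    element = trimws(elem),
    name = trimws(a$elety),
    residue_name = trimws(a$resid),
    residue_index = a$resno,
    chain_id = as.character(a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bfactor = ifelse(is.na(a$b), 0, a$b)
  )
  counts <- chain_residue_counts(atoms)
  if (length(counts) < 2) stop("not a complex: file has a single chain")
  if (!is.null(peptide_chain_hint)) {
    if (!peptide_chain_hint %in% names(counts)) {
      stop("peptide chain hint '", peptide_chain_hint, "' not present")
    }
    pep <- peptide_chain_hint
  } else {
    cand <- counts[counts >= 8 & counts <= 11]
    if (length(cand) == 0) {
      stop("peptide chain unresolvable: no chain with 8-11 residues and no hint")
    }
    if (length(cand) > 1) {
      warning("multiple chains with 8-11 residues (",
              paste(names(cand), collapse = ", "),
              "); choosing the shortest")
    }
    pep <- names(cand)[order(cand, names(cand))][1]
  }
  rest <- counts[setdiff(names(counts), pep)]
  hla <- names(rest)[which.max(rest)]
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  phla_complex(id = id, atoms = atoms, peptide_chain = pep, hla_chain = hla,
               peptide_sequence = chain_sequence(atoms, pep))
}

#' Read or template a dataset manifest
#'
#' A manifest is a CSV/TSV with columns `path`, `peptide`, and optionally
#' `label` (logical cross-reactivity) and `response` (free-text response
#' level). Paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest file path.
#' @return A tibble with columns `path` (absolute), `peptide`, `label`,
#'   `response`.
#' @export
read_manifest <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("path", "peptide") %in% names(df))) {
    stop("manifest must have columns 'path' and 'peptide'")
  }
  if (anyDuplicated(df$peptide)) stop("manifest peptide ids must be unique")
  root <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^/", df$path), df$path, file.path(root, df$path))
  tibble::tibble(
    path = abs,
    peptide = df$peptide,
    label = if ("label" %in% names(df)) as.logical(df$label) else NA,
    response = if ("response" %in% names(df)) df$response else NA_character_
  )
}
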