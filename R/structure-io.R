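# Protein structures are light S3 containers around two tibbles:
#   $atoms   - protein atoms (one row per atom)
#   $ligands - hetero-group heavy atoms (one row per atom)
# Both carry a `res_key` ("chain:resno[:icode]") so every downstream stage
# can address residues uniformly.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
DEFAULT_SOLVENT <- c("HOH", "WAT", "DOD")
DEFAULT_IONS <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "CU", "SO4", "PO4")

#' Residue key strings
#'
#' Builds the canonical "chain:resno" (or "chain:resno:icode") key used to
#' address residues throughout the package.
#'
#' @param chain,resno,icode Chain id, residue number, insertion code
#'   (empty string when absent).
#' @return Character vector of keys.
#' @export
res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == "", "", paste0(":", icode))
  paste0(chain, ":", resno, icode)
}

new_structure <- function(atoms, ligands, source = "structure") {
  atoms <- tibble::as_tibble(atoms)
  ligands <- tibble::as_tibble(ligands)
  # residue keys must be unique as (chain, resno, icode) combinations
  res <- dplyr::distinct(atoms, .data$chain, .data$resno, .data$icode, .data$resid)
  dup <- duplicated(res[c("chain", "resno", "icode")])
  if (any(dup)) {
    stop("duplicate residue key in structure: ", res_key(res$chain[dup][1], res$resno[dup][1], res$icode[dup][1]))
  }
  coord_dup <- atoms |>
    dplyr::group_by(.data$res_key) |>
    dplyr::filter(duplicated(paste(.data$x, .data$y, .data$z))) |>
    dplyr::ungroup()
  if (nrow(coord_dup) > 0) {
    stop("two atoms share identical coordinates within residue ", coord_dup$res_key[1])
  }
  structure(
    list(source = source, atoms = atoms, ligands = ligands),
    class = "pocket_structure"
  )
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (first model only), discards hydrogens and
#' solvent, resolves alternate locations to the highest-occupancy copy
#' (ties broken by file order), assigns van der Waals radii by element and
#' separates protein residues from hetero (ligand) groups.
#'
#' @param path Path to a PDB file.
#' @param radii Radius table, see [vdw_radius_table()].
#' @param solvent,ions Hetero residue names treated as solvent/ions and
#'   discarded rather than kept as ligands.
#' @param source Identifier stored with the structure; defaults to the
#'   file name without extension.
#' @return A `pocket_structure`: list with `$source`, `$atoms` and
#'   `$ligands` tibbles (columns `chain`, `resno`, `icode`, `resid`,
#'   `elety`, `element`, `x`, `y`, `z`, `vdw`, `is_backbone`, `res_key`;
#'   ligands additionally `ligand_id`).
#' @export
read_structure <- function(path, radii = vdw_radius_table(),
                           solvent = DEFAULT_SOLVENT, ions = DEFAULT_IONS,
                           source = NULL) {
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- tibble::as_tibble(pdb$atom)
  a$icode <- ifelse(is.na(a$insert) | a$insert == "", "", a$insert)
  a$chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  a$element <- toupper(ifelse(is.na(a$elesy) | a$elesy == "",
    substr(gsub("[0-9'\"]", "", a$elety), 1, 1), a$elesy
  ))
  a <- a[!(a$element %in% c("H", "D")), ]
  a <- a[!(a$resid %in% solvent), ]
  # altloc resolution: highest occupancy, ties -> first in file
  a$o[is.na(a$o)] <- 1
  a <- a |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$.file_order, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.file_order)
  if (any(!is.finite(a$x)) || any(!is.finite(a$y)) || any(!is.finite(a$z))) {
    stop("non-finite coordinates in ", path)
  }
  a$vdw <- assign_vdw(a$element, paste(a$resid, a$resno, a$elety), radii)
  a$res_key <- res_key(a$chain, a$resno, a$icode)
  a$is_backbone <- a$elety %in% BACKBONE_ATOMS
  cols <- c(
    "chain", "resno", "icode", "resid", "elety", "element",
    "x", "y", "z", "vdw", "is_backbone", "res_key"
  )
  prot <- a[a$type == "ATOM", cols]
  het <- a[a$type == "HETATM" & !(a$resid %in% ions), cols]
  het$is_backbone <- FALSE
  het$ligand_id <- paste0(het$resid, "_", het$res_key)
  new_structure(prot, het, source = source)
}

#' Write a structure as a PDB file
#'
#' Protein atoms become ATOM records, ligand atoms HETATM records.
#' Coordinates are written at standard PDB precision (0.001 Angstrom).
#'
#' @param x A `pocket_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "pocket_structure"))
  lig <- x$ligands
  if (nrow(lig) > 0) lig <- lig[names(x$atoms)]
  all <- dplyr::bind_rows(x$atoms, lig)
  type <- rep(c("ATOM", "HETATM"), c(nrow(x$atoms), nrow(lig)))
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(all[, c("x", "y", "z")]))),
    type = type,
    resno = all$resno, resid = all$resid, chain = all$chain,
    insert = ifelse(all$icode == "", NA, all$icode),
    eleno = seq_len(nrow(all)), elety = all$elety,
    elesy = all$element,
    o = rep(1, nrow(all)), b = rep(0, nrow(all))
  )
  invisible(path)
}

#' @export
print.pocket_structure <- function(x, ...) {
  cat(
    "<pocket_structure>", x$source, "-",
    length(unique(x$atoms$res_key)), "residues,",
    nrow(x$atoms), "protein atoms,",
    length(unique(x$ligands$ligand_id)), "ligand group(s)\n"
  )
  invisible(x)
}

#' Residue table of a structure
#'
#' @param x A `pocket_structure`.
#' @return Tibble with one row per protein residue (`chain`, `resno`,
#'   `icode`, `resid`, `res_key`), in chain/number order.
#' @export
residue_table <- function(x) {
  x$atoms |>
    dplyr::distinct(.data$chain, .data$resno, .data$icode, .data$resid, .data$res_key) |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode)
}

# Atoms of a subset of residues, as a tibble.
atoms_of <- function(x, keys) x$atoms[x$atoms$res_key %in% keys, ]

# n x 3 coordinate matrix from an atom tibble.
coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])
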