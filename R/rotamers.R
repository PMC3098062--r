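#' Clash-test parameters
#'
#' Two atoms clash when their distance falls below the sum of their van der
#' Waals radii minus the clash tolerance distance (CTD). The CTD softens
#' the test to tolerate coordinate uncertainty.
#'
#' @param ctd Clash tolerance distance in Angstrom (default 1.0).
#' @param radii Radius table, see [vdw_radius_table()].
#' @return List with `ctd` and `radii`.
#' @export
clash_params <- function(ctd = 1.0, radii = vdw_radius_table()) {
  stopifnot(ctd >= 0)
  list(ctd = ctd, radii = radii)
}

#' Steric clash between two atoms
#'
#' `TRUE` iff `dist(a1, a2) < vdw(a1) + vdw(a2) - CTD`.
#'
#' @param a1,a2 Single-row atom tibbles (or lists) with `x`, `y`, `z`,
#'   `vdw`.
#' @param params See [clash_params()].
#' @return Logical scalar.
#' @export
clash <- function(a1, a2, params = clash_params()) {
  d <- sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2 + (a1$z - a2$z)^2)
  d < a1$vdw + a2$vdw - params$ctd
}

# Vectorised clash test: any pair between atom sets 1 and 2 clashing,
# optionally masking excluded (bonded) pairs. Returns the logical clash
# matrix when `full = TRUE`, else a scalar.
clash_any <- function(xyz1, vdw1, xyz2, vdw2, ctd, exclude = NULL, full = FALSE) {
  if (nrow(xyz1) == 0 || nrow(xyz2) == 0) {
    return(if (full) matrix(FALSE, nrow(xyz1), nrow(xyz2)) else FALSE)
  }
  d2 <- cross_dist2(xyz1, xyz2)
  thr <- outer(vdw1, vdw2, "+") - ctd
  thr[thr < 0] <- 0
  cl <- d2 < thr^2
  if (!is.null(exclude)) cl[exclude] <- FALSE
  if (full) cl else any(cl)
}

#' Load a backbone-independent rotamer library
#'
#' Reads a tab-separated file with columns `res_name`, `rotamer_id`,
#' `chi1`..`chi4` (degrees; unused chi columns empty/NA) and an optional
#' `probability`. Angles are normalised to (-180, 180]. Each row must carry
#' exactly the number of chi values its residue type requires.
#'
#' @param path Path to the TSV file.
#' @return Rotamer library tibble, one row per rotamer.
#' @export
load_rotamer_library <- function(path) {
  lib <- readr::read_tsv(path, show_col_types = FALSE)
  validate_rotamer_library(lib, context = path)
}

validate_rotamer_library <- function(lib, context = "rotamer library") {
  need <- c("res_name", "rotamer_id", paste0("chi", 1:4))
  miss <- setdiff(need, names(lib))
  if (length(miss) > 0) stop(context, ": missing column(s) ", paste(miss, collapse = ", "))
  if (!("probability" %in% names(lib))) lib$probability <- NA_real_
  counts <- chi_counts()
  for (r in seq_len(nrow(lib))) {
    type <- lib$res_name[r]
    nchi <- counts[[type]]
    if (is.null(nchi)) stop(context, " row ", r, ": unknown residue type ", type)
    chis <- as.numeric(lib[r, paste0("chi", 1:4)])
    if (any(is.na(chis[seq_len(nchi)])) ||
      (nchi < 4 && any(!is.na(chis[(nchi + 1):4])))) {
      stop(context, " row ", r, ": ", type, " requires exactly ", nchi, " chi angle(s)")
    }
  }
  lib |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("chi"), ~ ifelse(is.na(.x), NA_real_, normalize_angle(.x)))) |>
    tibble::as_tibble()
}

#' Write a rotamer library TSV
#'
#' @param lib Rotamer library tibble (as from [load_rotamer_library()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rotamer_library <- function(lib, path) {
  readr::write_tsv(lib, path, na = "")
  invisible(path)
}

# Chi angles of one rotamer row as a plain numeric vector.
chi_of <- function(lib_row) {
  nchi <- chi_counts()[[lib_row$res_name]]
  as.numeric(lib_row[paste0("chi", seq_len(nchi))])
}

#' Build side-chain coordinates from chi angles
#'
#' Places the side chain of a residue by sequential internal-coordinate
#' construction: C-beta from the backbone (reused if present in the input,
#' else built at ideal tetrahedral geometry), then every further atom from
#' the ideal bond/angle table with dihedrals given by the chi angles. The
#' measured chi dihedrals of the result equal the inputs.
#'
#' @param residue_atoms Atom tibble of one residue (backbone `N`, `CA`,
#'   `C` required; `CB` reused if present).
#' @param res_type Three-letter residue type with a topology (see
#'   [chi_counts()]).
#' @param chi Numeric vector of chi angles in degrees.
#' @param radii Radius table for the placed atoms.
#' @return Atom tibble of the side chain (C-beta and beyond), inheriting
#'   residue identifiers from the input.
#' @export
apply_rotamer <- function(residue_atoms, res_type, chi, radii = vdw_radius_table()) {
  topo <- sidechain_topologies()[[res_type]]
  if (is.null(topo)) stop("unknown or chi-less residue type: ", res_type)
  nchi <- chi_counts()[[res_type]]
  if (length(chi) != nchi) {
    stop(res_type, " needs ", nchi, " chi angle(s), got ", length(chi))
  }
  at <- function(e) {
    row <- residue_atoms[residue_atoms$elety == e, ]
    if (nrow(row) == 0) stop("residue lacks backbone atom ", e)
    as.numeric(row[1, c("x", "y", "z")])
  }
  pos <- list(N = at("N"), CA = at("CA"), C = at("C"))
  cb_row <- residue_atoms[residue_atoms$elety == "CB", ]
  pos$CB <- if (nrow(cb_row) > 0) {
    as.numeric(cb_row[1, c("x", "y", "z")])
  } else {
    build_cb(pos$N, pos$CA, pos$C)
  }
  for (r in seq_len(nrow(topo))) {
    dih <- if (is.na(topo$chi[r])) topo$offset[r] else chi[topo$chi[r]] + topo$offset[r]
    pos[[topo$atom[r]]] <- place_atom(
      pos[[topo$ref3[r]]], pos[[topo$ref2[r]]], pos[[topo$ref1[r]]],
      topo$bond[r], topo$angle[r], normalize_angle(dih)
    )
  }
  names_out <- c("CB", topo$atom)
  elements <- c("C", topo$element)
  xyz <- do.call(rbind, pos[names_out])
  proto <- residue_atoms[residue_atoms$elety == "CA", ][1, ]
  out <- proto[rep(1, length(names_out)), ]
  out$elety <- names_out
  out$element <- elements
  out$x <- xyz[, 1]
  out$y <- xyz[, 2]
  out$z <- xyz[, 3]
  out$vdw <- assign_vdw(elements, names_out, radii)
  out$is_backbone <- FALSE
  out$resid <- res_type
  out
}

#' Measure chi angles of a residue
#'
#' @param residue_atoms Atom tibble of one residue with full side chain.
#' @param res_type Three-letter residue type.
#' @return Numeric vector of chi angles in degrees.
#' @export
measure_chi <- function(residue_atoms, res_type) {
  topo <- sidechain_topologies()[[res_type]]
  if (is.null(topo)) stop("unknown or chi-less residue type: ", res_type)
  at <- function(e) {
    row <- residue_atoms[residue_atoms$elety == e, ]
    if (nrow(row) == 0) stop("missing atom ", e, " for chi measurement")
    as.numeric(row[1, c("x", "y", "z")])
  }
  defs <- topo[!is.na(topo$chi) & topo$offset == 0, ]
  vapply(seq_len(chi_counts()[[res_type]]), function(k) {
    row <- defs[defs$chi == k, ][1, ]
    dihedral_angle(at(row$ref3), at(row$ref2), at(row$ref1), at(row$atom))
  }, numeric(1))
}

# Bonded-pair exclusion mask between the side chain of residue `key` and a
# fixed-atom table: pairs separated by <= 3 bonds are never clash-tested.
# Side-chain depth from CA + backbone distance from CA <= 3 covers the
# intra-residue cases; across the peptide bond only CB vs the previous C
# and the next N are within 3 bonds.
bonded_exclusion <- function(sc_atoms, res_type, fixed) {
  depth <- sidechain_depths(res_type)[sc_atoms$elety]
  dist_ca <- c(N = 1L, CA = 0L, C = 1L, O = 2L, OXT = 2L)
  key <- sc_atoms$res_key[1]
  chain <- sc_atoms$chain[1]
  resno <- sc_atoms$resno[1]
  same <- fixed$res_key == key
  bb_d <- unname(dist_ca[fixed$elety])
  bb_d[is.na(bb_d)] <- 99L
  excl_same <- outer(depth, ifelse(same, bb_d, 99L), "+") <= 3L
  adj <- (fixed$chain == chain & fixed$resno == resno - 1L & fixed$elety == "C") |
    (fixed$chain == chain & fixed$resno == resno + 1L & fixed$elety == "N")
  excl_adj <- outer(depth == 1L, adj, "&")
  excl_same | excl_adj
}

#' Prefilter rotamers against the fixed environment
#'
#' Builds every library rotamer on every second-layer residue and discards
#' those whose side chain clashes with the fixed atoms: all backbone atoms
#' plus the side chains of residues that are not second-layer residues.
#' Pairs separated by three or fewer covalent bonds (own backbone, the
#' peptide-bond neighbours of C-beta) are exempt, as usual for soft steric
#' tests. Surviving rotamers keep their library order.
#'
#' @param structure Original `pocket_structure` (side chains present).
#' @param library Rotamer library tibble.
#' @param slr_keys Second-layer residue keys (the flexible set).
#' @param params See [clash_params()].
#' @return A `rotamer_placements` object: list with `residues` (sorted
#'   keys), `rotamer_ids` (per residue, surviving library rotamer ids),
#'   `placements` (per residue, list of side-chain atom tibbles) and
#'   `params`.
#' @export
prefilter_rotamers <- function(structure, library, slr_keys, params = clash_params()) {
  keys <- sort(slr_keys)
  res_tbl <- residue_table(structure)
  fixed <- structure$atoms[
    structure$atoms$is_backbone | !(structure$atoms$res_key %in% keys),
  ]
  fxyz <- coords(fixed)
  placements <- list()
  rotamer_ids <- list()
  for (k in keys) {
    ratoms <- structure$atoms[structure$atoms$res_key == k, ]
    type <- ratoms$resid[1]
    if (!all(c("N", "CA", "C") %in% ratoms$elety)) {
      stop("residue ", k, " flagged flexible but lacks backbone atoms")
    }
    rots <- library[library$res_name == type, ]
    if (nrow(rots) == 0) stop("rotamer library has no entries for ", type, " (residue ", k, ")")
    keep_pl <- list()
    keep_id <- c()
    for (r in seq_len(nrow(rots))) {
      pl <- apply_rotamer(ratoms, type, chi_of(rots[r, ]), radii = params$radii)
      excl <- bonded_exclusion(pl, type, fixed)
      if (!clash_any(coords(pl), pl$vdw, fxyz, fixed$vdw, params$ctd, exclude = excl)) {
        keep_pl[[length(keep_pl) + 1]] <- pl
        keep_id <- c(keep_id, rots$rotamer_id[r])
      }
    }
    if (length(keep_pl) == 0) {
      stop(
        "residue ", k, " (", type, ") has no rotamer compatible with the ",
        "fixed atoms; the pocket cannot be built"
      )
    }
    placements[[k]] <- keep_pl
    rotamer_ids[[k]] <- keep_id
  }
  structure(
    list(
      residues = keys, rotamer_ids = rotamer_ids,
      placements = placements, params = params
    ),
    class = "rotamer_placements"
  )
}

#' @export
print.rotamer_placements <- function(x, ...) {
  n <- vapply(x$placements, length, integer(1))
  cat(
    "<rotamer_placements>", length(x$residues), "residues,",
    paste(n, collapse = "/"), "surviving rotamers\n"
  )
  invisible(x)
}
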