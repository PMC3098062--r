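#' Select first-layer residues (FLRs)
#'
#' First-layer residues are the protein residues with at least one atom
#' within `cutoff` of at least one atom of the pooled ligand ensemble.
#' They delimit the binding site: their side chains are subsequently
#' shaved to alanine to expose the maximally expanded pocket.
#'
#' @param template A `pocket_structure` (template frame).
#' @param ensemble Ligand ensemble tibble from [build_ligand_ensemble()].
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return Tibble of residues (as [residue_table()]) sorted by key.
#' @export
select_flr <- function(template, ensemble, cutoff = 5.0) {
  if (nrow(ensemble) == 0) {
    stop(
      "empty ligand ensemble: in apo-template mode supply the first-layer ",
      "residue list manually instead of calling select_flr()"
    )
  }
  d <- min_dist(coords(template$atoms), coords(ensemble))
  keys <- unique(template$atoms$res_key[d < cutoff])
  out <- residue_table(template) |> dplyr::filter(.data$res_key %in% keys)
  if (nrow(out) == 0) {
    stop("no residue within ", cutoff, " A of the ligand ensemble; check the superposition")
  }
  out
}

# Ideal geometry used when a C-beta has to be rebuilt from the backbone and
# by the side-chain builder's common root. Values are standard ideal
# bond/angle terms; the improper C-N-CA-CB torsion fixes L chirality.
ideal_cb_geometry <- function() {
  list(bond = 1.53, angle = 110.5, improper = 122.6)
}

build_cb <- function(n, ca, c, geom = ideal_cb_geometry()) {
  place_atom(c, n, ca, geom$bond, geom$angle, geom$improper)
}

#' Substitute residues by alanine
#'
#' Removes all side-chain atoms beyond C-beta for the given residues,
#' keeping (or rebuilding at ideal tetrahedral geometry) the C-beta, and
#' renames them ALA. Glycine is left untouched. Proline is substituted like
#' any other residue, with a message, since its backbone stays fixed.
#' The input structure is not modified.
#'
#' @param x A `pocket_structure`.
#' @param keys Residue keys to substitute (e.g. from [select_flr()]).
#' @return A new `pocket_structure` with enlarged pocket.
#' @export
ala_substitute <- function(x, keys) {
  missing <- setdiff(keys, x$atoms$res_key)
  if (length(missing) > 0) stop("unknown residue key(s): ", paste(missing, collapse = ", "))
  res <- residue_table(x)
  out <- vector("list", length(keys))
  keep <- !(x$atoms$res_key %in% keys)
  carbon_vdw <- assign_vdw("C")
  for (i in seq_along(keys)) {
    k <- keys[i]
    ratoms <- x$atoms[x$atoms$res_key == k, ]
    rname <- ratoms$resid[1]
    if (rname == "GLY") {
      out[[i]] <- ratoms
      next
    }
    if (rname == "PRO") {
      message("ala_substitute: substituting proline ", k, " (fixed backbone assumed)")
    }
    bb <- ratoms[ratoms$elety %in% BACKBONE_ATOMS, ]
    if (!all(c("N", "CA", "C") %in% bb$elety)) {
      stop("residue ", k, " lacks backbone atoms required for substitution")
    }
    cb <- ratoms[ratoms$elety == "CB", ]
    if (nrow(cb) == 0) {
      at <- function(e) as.numeric(ratoms[ratoms$elety == e, c("x", "y", "z")][1, ])
      pos <- build_cb(at("N"), at("CA"), at("C"))
      cb <- ratoms[ratoms$elety == "CA", ][1, ]
      cb$elety <- "CB"
      cb$element <- "C"
      cb$vdw <- carbon_vdw
      cb$is_backbone <- FALSE
      cb$x <- pos[1]
      cb$y <- pos[2]
      cb$z <- pos[3]
    }
    sub <- dplyr::bind_rows(bb, cb)
    sub$resid <- "ALA"
    out[[i]] <- sub
  }
  atoms <- dplyr::bind_rows(x$atoms[keep, ], out) |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode)
  new_structure(atoms, x$ligands, source = x$source)
}
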