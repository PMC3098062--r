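# Internal-coordinate topologies for side-chain construction.
#
# Each atom beyond C-beta is placed by place_atom(ref3, ref2, ref1, bond,
# angle, dihedral) where ref1 is the bonded parent, ref2 the angle
# reference and ref3 the dihedral reference. `chi` names the chi angle the
# dihedral depends on (dihedral = chi_k + offset); `chi = NA` means a fixed
# dihedral equal to `offset` (ring closures, amide/guanidinium planarity).
# Bond lengths and angles are standard ideal values; C-beta itself is
# handled by build_cb() / the backbone.

sc_row <- function(atom, element, ref1, ref2, ref3, bond, angle, chi, offset) {
  tibble::tibble(
    atom = atom, element = element, ref1 = ref1, ref2 = ref2, ref3 = ref3,
    bond = bond, angle = angle, chi = chi, offset = offset
  )
}

sidechain_topologies <- function() {
  t <- list()
  t$SER <- sc_row("OG", "O", "CB", "CA", "N", 1.42, 110.8, 1L, 0)
  t$CYS <- sc_row("SG", "S", "CB", "CA", "N", 1.81, 113.8, 1L, 0)
  t$VAL <- dplyr::bind_rows(
    sc_row("CG1", "C", "CB", "CA", "N", 1.52, 110.5, 1L, 0),
    sc_row("CG2", "C", "CB", "CA", "N", 1.52, 110.5, 1L, 122.3)
  )
  t$THR <- dplyr::bind_rows(
    sc_row("OG1", "O", "CB", "CA", "N", 1.43, 109.6, 1L, 0),
    sc_row("CG2", "C", "CB", "CA", "N", 1.52, 110.5, 1L, -122.3)
  )
  t$LEU <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.53, 116.3, 1L, 0),
    sc_row("CD1", "C", "CG", "CB", "CA", 1.52, 110.7, 2L, 0),
    sc_row("CD2", "C", "CG", "CB", "CA", 1.52, 110.7, 2L, -122.3)
  )
  t$ILE <- dplyr::bind_rows(
    sc_row("CG1", "C", "CB", "CA", "N", 1.53, 110.4, 1L, 0),
    sc_row("CG2", "C", "CB", "CA", "N", 1.52, 110.5, 1L, -122.3),
    sc_row("CD1", "C", "CG1", "CB", "CA", 1.52, 113.9, 2L, 0)
  )
  t$ASP <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 112.6, 1L, 0),
    sc_row("OD1", "O", "CG", "CB", "CA", 1.25, 118.4, 2L, 0),
    sc_row("OD2", "O", "CG", "CB", "CA", 1.25, 118.4, 2L, 180)
  )
  t$ASN <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 112.6, 1L, 0),
    sc_row("OD1", "O", "CG", "CB", "CA", 1.23, 120.8, 2L, 0),
    sc_row("ND2", "N", "CG", "CB", "CA", 1.33, 116.4, 2L, 180)
  )
  t$GLU <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
    sc_row("CD", "C", "CG", "CB", "CA", 1.52, 112.6, 2L, 0),
    sc_row("OE1", "O", "CD", "CG", "CB", 1.25, 118.4, 3L, 0),
    sc_row("OE2", "O", "CD", "CG", "CB", 1.25, 118.4, 3L, 180)
  )
  t$GLN <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
    sc_row("CD", "C", "CG", "CB", "CA", 1.52, 112.6, 2L, 0),
    sc_row("OE1", "O", "CD", "CG", "CB", 1.23, 120.8, 3L, 0),
    sc_row("NE2", "N", "CD", "CG", "CB", 1.33, 116.4, 3L, 180)
  )
  t$MET <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
    sc_row("SD", "S", "CG", "CB", "CA", 1.80, 112.7, 2L, 0),
    sc_row("CE", "C", "SD", "CG", "CB", 1.79, 100.9, 3L, 0)
  )
  t$LYS <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
    sc_row("CD", "C", "CG", "CB", "CA", 1.52, 111.3, 2L, 0),
    sc_row("CE", "C", "CD", "CG", "CB", 1.52, 111.3, 3L, 0),
    sc_row("NZ", "N", "CE", "CD", "CG", 1.49, 111.9, 4L, 0)
  )
  t$ARG <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
    sc_row("CD", "C", "CG", "CB", "CA", 1.52, 111.3, 2L, 0),
    sc_row("NE", "N", "CD", "CG", "CB", 1.46, 111.5, 3L, 0),
    sc_row("CZ", "C", "NE", "CD", "CG", 1.33, 124.2, 4L, 0),
    sc_row("NH1", "N", "CZ", "NE", "CD", 1.33, 120.0, NA, 0),
    sc_row("NH2", "N", "CZ", "NE", "CD", 1.33, 120.0, NA, 180)
  )
  t$PHE <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.50, 113.8, 1L, 0),
    sc_row("CD1", "C", "CG", "CB", "CA", 1.39, 120.8, 2L, 0),
    sc_row("CD2", "C", "CG", "CB", "CA", 1.39, 120.8, 2L, 180),
    sc_row("CE1", "C", "CD1", "CG", "CB", 1.39, 120.8, NA, 180),
    sc_row("CE2", "C", "CD2", "CG", "CB", 1.39, 120.8, NA, 180),
    sc_row("CZ", "C", "CE1", "CD1", "CG", 1.39, 120.0, NA, 0)
  )
  t$TYR <- dplyr::bind_rows(
    t$PHE,
    sc_row("OH", "O", "CZ", "CE1", "CD1", 1.38, 119.9, NA, 180)
  )
  t$HIS <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.49, 113.8, 1L, 0),
    sc_row("ND1", "N", "CG", "CB", "CA", 1.38, 122.7, 2L, 0),
    sc_row("CD2", "C", "CG", "CB", "CA", 1.36, 131.1, 2L, 180),
    sc_row("CE1", "C", "ND1", "CG", "CB", 1.32, 109.2, NA, 180),
    sc_row("NE2", "N", "CD2", "CG", "CB", 1.37, 107.2, NA, 180)
  )
  t$TRP <- dplyr::bind_rows(
    sc_row("CG", "C", "CB", "CA", "N", 1.50, 113.6, 1L, 0),
    sc_row("CD1", "C", "CG", "CB", "CA", 1.37, 126.9, 2L, 0),
    sc_row("CD2", "C", "CG", "CB", "CA", 1.43, 126.7, 2L, 180),
    sc_row("NE1", "N", "CD1", "CG", "CB", 1.38, 110.2, NA, 180),
    sc_row("CE2", "C", "CD2", "CG", "CB", 1.41, 107.2, NA, 180),
    sc_row("CE3", "C", "CD2", "CG", "CB", 1.40, 133.9, NA, 0),
    sc_row("CZ2", "C", "CE2", "CD2", "CG", 1.40, 122.4, NA, 180),
    sc_row("CZ3", "C", "CE3", "CD2", "CG", 1.39, 118.6, NA, 180),
    sc_row("CH2", "C", "CZ2", "CE2", "CD2", 1.37, 117.5, NA, 180)
  )
  t
}

#' Number of chi angles per residue type
#'
#' @return Named integer vector over the 17 chi-bearing standard residue
#'   types (Gly and Ala carry no side-chain dihedral; Pro is treated as
#'   rigid).
#' @export
chi_counts <- function() {
  c(
    SER = 1L, CYS = 1L, VAL = 1L, THR = 1L,
    LEU = 2L, ILE = 2L, ASP = 2L, ASN = 2L, PHE = 2L, TYR = 2L,
    HIS = 2L, TRP = 2L,
    MET = 3L, GLU = 3L, GLN = 3L,
    LYS = 4L, ARG = 4L
  )
}

# Bond-path depth of each side-chain atom from CA (CB = 1, gamma = 2, ...),
# used for the 1-2/1-3/1-4 bonded exclusions in clash tests.
sidechain_depths <- function(res_type) {
  topo <- sidechain_topologies()[[res_type]]
  depth <- c(CB = 1L)
  if (!is.null(topo)) {
    for (r in seq_len(nrow(topo))) {
      depth[topo$atom[r]] <- depth[[topo$ref1[r]]] + 1L
    }
  }
  depth
}
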