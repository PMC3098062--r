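#' Van der Waals radius table
#'
#' Bondi-style element radii used for steric clash tests, lattice carving
#' and point-contact tests. The set is deliberately small: structures are
#' heavy-atom only (hydrogens are discarded on input), so only elements that
#' occur in amino acids and common ligands are listed. A custom table with
#' the same columns can be passed to any function that takes `radii`.
#'
#' @return A tibble with columns `element` (symbol, upper case) and
#'   `radius` (Angstrom).
#' @examples
#' vdw_radius_table()
#' @export
vdw_radius_table <- function() {
  tibble::tibble(
    element = c("C", "N", "O", "S", "P", "F", "CL", "BR", "I", "SE", "B"),
    radius  = c(1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98, 1.90, 1.92)
  )
}

# Look up radii for a vector of element symbols; unknown elements are a hard
# error naming the offending atom so silently wrong sterics are impossible.
assign_vdw <- function(element, atom_label = element, radii = vdw_radius_table()) {
  idx <- match(toupper(element), radii$element)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(
      "unknown element '", element[bad], "' for atom ", atom_label[bad],
      "; extend the radius table to cover it"
    )
  }
  radii$radius[idx]
}
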