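# Shared fixtures, built once per test run. The default toy system and
# its full pipeline result are cached because several files assert
# against different stages of the same run.

.fixture_env <- new.env(parent = emptyenv())

toy_system <- function() {
  if (is.null(.fixture_env$sys)) {
    .fixture_env$sys <- make_toy_system(toy_spec())
  }
  .fixture_env$sys
}

toy_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    sys <- toy_system()
    .fixture_env$pipe <- suppressMessages(run_pipeline(
      sys$template, sys$holo, sys$library,
      config = run_config(k = 4)
    ))
  }
  .fixture_env$pipe
}

# A minimal hand-buildable structure: residues given as a list of lists
# with fields chain, resno, resid and a named list of atom positions.
mini_structure <- function(residues, ligand_atoms = NULL, source = "mini") {
  rows <- lapply(residues, function(r) {
    elety <- names(r$atoms)
    element <- substr(gsub("[0-9]", "", elety), 1, 1)
    xyz <- do.call(rbind, r$atoms)
    tibble::tibble(
      chain = r$chain, resno = as.integer(r$resno), icode = "",
      resid = r$resid, elety = elety, element = element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      vdw = vdw_radius_table()$radius[match(
        element,
        vdw_radius_table()$element
      )],
      is_backbone = elety %in% c("N", "CA", "C", "O", "OXT"),
      res_key = res_key(r$chain, r$resno)
    )
  })
  atoms <- dplyr::bind_rows(rows)
  lig <- if (is.null(ligand_atoms)) {
    dplyr::mutate(atoms[0, ], ligand_id = character(0))
  } else {
    ligand_atoms
  }
  pocketshapes:::new_structure(atoms, lig, source = source)
}

# One residue with an ideal backbone at the origin, for rotamer tests.
ideal_residue <- function(resid = "LEU", chain = "A", resno = 1) {
  th <- 55.5 * pi / 180
  list(
    chain = chain, resno = resno, resid = resid,
    atoms = list(
      N = 1.46 * c(cos(th), sin(th), 0),
      CA = c(0, 0, 0),
      C = 1.52 * c(cos(th), -sin(th), 0),
      O = 1.52 * c(cos(th), -sin(th), 0) + c(0, -1.1, 0.6)
    )
  )
}

# Ligand ensemble tibble from a bare coordinate matrix of carbons.
carbon_ensemble <- function(xyz, id = "LIG") {
  xyz <- matrix(xyz, ncol = 3)
  tibble::tibble(
    source = "mini", ligand_id = id,
    chain = "L", resno = 900L, icode = "", resid = id,
    elety = paste0("C", seq_len(nrow(xyz))), element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw = 1.70, is_backbone = FALSE, res_key = "L:900"
  )
}

# Fixed-column PDB ATOM/HETATM line for handcrafted parser fixtures.
pdb_line <- function(record, serial, name, alt, resn, chain, resno, x, y, z,
                     occ = 1, b = 0, element = "C") {
  sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
    alt, resn, chain, resno, x, y, z, occ, b, element
  )
}
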