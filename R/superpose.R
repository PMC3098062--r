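#' Rigid-body backbone superposition (Kabsch)
#'
#' Least-squares superposition of the mobile structure onto the template
#' over C-alpha atoms matched by (chain, residue number, insertion code).
#' The returned transform maps mobile coordinates into the template frame:
#' `y = x %*% rotation + translation` for row coordinate vectors.
#'
#' @param mobile,template `pocket_structure` objects of the same protein.
#' @return A `superposition`: list with `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom over matched C-alpha) and
#'   `n_matched`.
#' @export
superpose_backbone <- function(mobile, template) {
  ca_m <- mobile$atoms[mobile$atoms$elety == "CA", ]
  ca_t <- template$atoms[template$atoms$elety == "CA", ]
  common <- intersect(ca_m$res_key, ca_t$res_key)
  if (length(common) < 3) {
    stop("need at least 3 matched C-alpha pairs, got ", length(common))
  }
  x <- coords(ca_m[match(common, ca_m$res_key), ])
  y <- coords(ca_t[match(common, ca_t$res_key), ])
  xm <- colMeans(x)
  ym <- colMeans(y)
  xc <- sweep(x, 2, xm)
  yc <- sweep(y, 2, ym)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- ym - drop(xm %*% rot)
  fitted <- sweep(x %*% rot, 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  structure(
    list(rotation = rot, translation = trans, rmsd = rmsd, n_matched = length(common)),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "<superposition> %d C-alpha matched, rmsd %.3f A\n",
    x$n_matched, x$rmsd
  ))
  invisible(x)
}

#' Apply a superposition transform to a structure
#'
#' Transforms all protein and ligand atom coordinates into the template
#' frame of the superposition.
#'
#' @param x A `pocket_structure`.
#' @param sp A `superposition` from [superpose_backbone()].
#' @return A transformed `pocket_structure`.
#' @export
apply_superposition <- function(x, sp) {
  stopifnot(inherits(sp, "superposition"))
  tf <- function(df) {
    if (nrow(df) == 0) return(df)
    xyz <- sweep(coords(df) %*% sp$rotation, 2, sp$translation, "+")
    df$x <- xyz[, 1]
    df$y <- xyz[, 2]
    df$z <- xyz[, 3]
    df
  }
  x$atoms <- tf(x$atoms)
  x$ligands <- tf(x$ligands)
  x
}

#' Pool ligand atoms from superposed structures
#'
#' Takes structures already expressed in the template frame and pools all
#' their ligand heavy atoms into one ensemble, keeping provenance. With no
#' ligand anywhere the result is an empty ensemble flagged apo: first-layer
#' residues must then be supplied manually (see [select_flr()]).
#'
#' @param structures List of superposed `pocket_structure` objects.
#' @return Tibble of ligand atoms with a `source` column; attribute
#'   `apo = TRUE` and a warning when empty.
#' @export
build_ligand_ensemble <- function(structures) {
  if (inherits(structures, "pocket_structure")) structures <- list(structures)
  ens <- purrr::map_dfr(structures, function(s) {
    if (nrow(s$ligands) == 0) return(NULL)
    dplyr::mutate(s$ligands, source = s$source, .before = 1)
  })
  if (nrow(ens) == 0) {
    warning("no ligand atoms in any structure; apo-template mode")
    ens <- tibble::tibble(
      source = character(), ligand_id = character(),
      x = numeric(), y = numeric(), z = numeric(), vdw = numeric()
    )
    attr(ens, "apo") <- TRUE
  } else {
    attr(ens, "apo") <- FALSE
  }
  ens
}
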