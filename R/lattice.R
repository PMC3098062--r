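# The pocket is mapped by a cubic lattice. Retained points are stored in a
# `pocket_lattice`: origin + spacing plus a tibble of integer index triples
# (i, j, k) and Cartesian coordinates. Point ids are assigned in
# lexicographic (i, j, k) order and never change afterwards, so bit
# positions derived from them are reproducible across runs.

new_lattice <- function(origin, spacing, ijk) {
  ord <- order(ijk[, 1], ijk[, 2], ijk[, 3])
  ijk <- ijk[ord, , drop = FALSE]
  pts <- tibble::tibble(
    id = seq_len(nrow(ijk)),
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    x = origin[1] + spacing * ijk[, 1],
    y = origin[2] + spacing * ijk[, 2],
    z = origin[3] + spacing * ijk[, 3]
  )
  structure(
    list(origin = origin, spacing = spacing, points = pts),
    class = "pocket_lattice"
  )
}

#' @export
print.pocket_lattice <- function(x, ...) {
  cat(
    "<pocket_lattice>", nrow(x$points), "points, spacing",
    x$spacing, "A\n"
  )
  invisible(x)
}

lattice_coords <- function(lattice) coords(lattice$points)

# Occupancy of the integer grid: TRUE where the grid point lies inside the
# van der Waals sphere of any atom. dims/off describe the grid: index triple
# (i,j,k) maps to array index (i-off[1]+1, ...).
occupancy_array <- function(atoms, origin, spacing, lo, hi) {
  dims <- hi - lo + 1L
  occ <- array(FALSE, dim = dims)
  ax <- coords(atoms)
  for (t in seq_len(nrow(ax))) {
    r <- atoms$vdw[t]
    ctr <- (ax[t, ] - origin) / spacing
    rng_lo <- pmax(lo, as.integer(ceiling(ctr - r / spacing)))
    rng_hi <- pmin(hi, as.integer(floor(ctr + r / spacing)))
    if (any(rng_lo > rng_hi)) next
    ii <- rng_lo[1]:rng_hi[1]
    jj <- rng_lo[2]:rng_hi[2]
    kk <- rng_lo[3]:rng_hi[3]
    g <- expand.grid(i = ii, j = jj, k = kk)
    d2 <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2
    inside <- d2 * spacing^2 < r^2
    if (!any(inside)) next
    idx <- cbind(g$i[inside] - lo[1] + 1L, g$j[inside] - lo[2] + 1L, g$k[inside] - lo[3] + 1L)
    occ[idx] <- TRUE
  }
  occ
}

# The seven scan-line directions: the 3 lattice axes and 4 body diagonals.
SCAN_DIRECTIONS <- rbind(
  c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
  c(1L, 1L, 1L), c(1L, -1L, 1L), c(1L, 1L, -1L), c(1L, -1L, -1L)
)

#' Generate the lattice points mapping the pocket
#'
#' Fills the alanine-enlarged binding pocket with a cubic lattice. A grid
#' point is retained iff it (a) lies outside the van der Waals sphere of
#' every protein atom, (b) passes the buriedness (cavity) test: along at
#' least `cavity_min_dirs` of the 7 scan directions (3 axes + 4 body
#' diagonals) the scan line hits protein on *both* sides within
#' `cavity_range`, and (c) lies within `trim_cutoff` of at least one
#' binding-site-residue atom or ligand-ensemble atom (atom centers).
#'
#' @param structure Ala-substituted `pocket_structure`.
#' @param ensemble Ligand ensemble tibble (may be empty in apo mode if
#'   `flr_keys` is given).
#' @param flr_keys First-layer residue keys: the "binding site residues"
#'   used for the trim test.
#' @param spacing Lattice spacing in Angstrom (default 1.0).
#' @param trim_cutoff Trim distance in Angstrom (default 6.0).
#' @param cavity_min_dirs Minimum number of protein-blocked scan directions
#'   for a point to count as inside the pocket (default 4 of 7).
#' @param cavity_range Maximum scan range along each direction, Angstrom.
#' @return A `pocket_lattice`.
#' @export
generate_pocket_points <- function(structure, ensemble, flr_keys,
                                   spacing = 1.0, trim_cutoff = 6.0,
                                   cavity_min_dirs = 4, cavity_range = 14.0) {
  stopifnot(spacing > 0)
  site_atoms <- atoms_of(structure, flr_keys)
  anchors <- rbind(coords(site_atoms), coords(ensemble))
  if (nrow(anchors) == 0) stop("no binding-site atoms or ensemble atoms to anchor the lattice")
  origin <- c(0, 0, 0)
  lo_box <- apply(anchors, 2, min) - trim_cutoff
  hi_box <- apply(anchors, 2, max) + trim_cutoff
  lo <- as.integer(floor(lo_box / spacing))
  hi <- as.integer(ceiling(hi_box / spacing))
  # occupancy over the box extended by the scan range so rays can be
  # evaluated by pure array lookups
  ext <- as.integer(ceiling(cavity_range / spacing))
  occ <- occupancy_array(structure$atoms, origin, spacing, lo - ext, hi + ext)
  off <- lo - ext
  dims <- dim(occ)

  g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  gi <- as.integer(g$i); gj <- as.integer(g$j); gk <- as.integer(g$k)
  at_idx <- cbind(gi - off[1] + 1L, gj - off[2] + 1L, gk - off[3] + 1L)
  free <- !occ[at_idx]

  # (c) trim first: cheap and shrinks the candidate set
  xyz <- cbind(gi, gj, gk) * spacing
  near <- rep(FALSE, nrow(xyz))
  cut2 <- trim_cutoff^2
  for (t in seq_len(nrow(anchors))) {
    d2 <- (xyz[, 1] - anchors[t, 1])^2 + (xyz[, 2] - anchors[t, 2])^2 + (xyz[, 3] - anchors[t, 3])^2
    near <- near | (d2 < cut2)
  }
  cand <- which(free & near)
  if (length(cand) == 0) stop("no lattice point survives the vdW and trim tests")

  # (b) buriedness scan
  ci <- gi[cand]; cj <- gj[cand]; ck <- gk[cand]
  n_blocked <- integer(length(cand))
  for (d in seq_len(nrow(SCAN_DIRECTIONS))) {
    dir <- SCAN_DIRECTIONS[d, ]
    step_len <- sqrt(sum(dir^2)) * spacing
    n_steps <- floor(cavity_range / step_len)
    blocked_pos <- rep(FALSE, length(cand))
    blocked_neg <- rep(FALSE, length(cand))
    for (s in seq_len(n_steps)) {
      for (sgn in c(1L, -1L)) {
        ii <- ci + sgn * s * dir[1] - off[1] + 1L
        jj <- cj + sgn * s * dir[2] - off[2] + 1L
        kk <- ck + sgn * s * dir[3] - off[3] + 1L
        ok <- ii >= 1L & ii <= dims[1] & jj >= 1L & jj <= dims[2] & kk >= 1L & kk <= dims[3]
        hit <- rep(FALSE, length(cand))
        hit[ok] <- occ[cbind(ii[ok], jj[ok], kk[ok])]
        if (sgn > 0) blocked_pos <- blocked_pos | hit else blocked_neg <- blocked_neg | hit
      }
    }
    n_blocked <- n_blocked + (blocked_pos & blocked_neg)
  }
  keep <- cand[n_blocked >= cavity_min_dirs]
  if (length(keep) == 0) stop("no lattice point passes the cavity test; pocket too open?")
  new_lattice(origin, spacing, cbind(gi[keep], gj[keep], gk[keep]))
}

#' Select second-layer residues (SLRs)
#'
#' A lattice point "contacts the first layer" when it satisfies the
#' point-atom contact rule (see [point_contact()]) against any atom of a
#' first-layer residue with its original side chain restored. Second-layer
#' residues are the residues - of any type except Gly and Ala, which carry
#' no rotamers - with at least one atom within `cutoff` of such a point.
#' They are the set whose rotamer combinations are enumerated.
#'
#' @param structure Original (not Ala-substituted) `pocket_structure`.
#' @param lattice A `pocket_lattice`.
#' @param flr_keys First-layer residue keys.
#' @param cutoff Distance cutoff in Angstrom (default 3.0).
#' @param params Contact parameters, see [contact_params()].
#' @return Tibble of residues sorted by key, as [residue_table()].
#' @export
select_slr <- function(structure, lattice, flr_keys, cutoff = 3.0,
                       params = contact_params()) {
  pts <- lattice_coords(lattice)
  flr_atoms <- atoms_of(structure, flr_keys)
  touch <- points_in_contact(pts, flr_atoms, params)
  if (!any(touch)) stop("no lattice point contacts the first-layer residues")
  contact_pts <- pts[touch, , drop = FALSE]
  d <- min_dist(coords(structure$atoms), contact_pts)
  keys <- unique(structure$atoms$res_key[d < cutoff])
  out <- residue_table(structure) |>
    dplyr::filter(.data$res_key %in% keys, !(.data$resid %in% c("GLY", "ALA")))
  if (nrow(out) == 0) stop("no second-layer residue found within ", cutoff, " A")
  out
}

#' Classify lattice points by contact behaviour over conformers
#'
#' Points contacted by every conformer are "always-contact" (inside the
#' wall in every shape), points contacted by none are "always-free", and
#' the remainder are "conditional": they discriminate conformers and
#' define, in lattice order, the bit positions of the shape fingerprint.
#'
#' @param lattice A `pocket_lattice`.
#' @param contact_sets List (one element per conformer) of integer vectors
#'   of contacted point ids.
#' @return A `pocket_points` object: list with `lattice`, `always_free`,
#'   `always_contact`, `conditional` (ordered id vectors partitioning the
#'   lattice) and `ccr_keys` (filled by [identify_ccrs()]).
#' @export
classify_points <- function(lattice, contact_sets) {
  if (length(contact_sets) == 0) stop("need at least one conformer contact set")
  all_ids <- lattice$points$id
  in_any <- Reduce(union, contact_sets)
  in_all <- Reduce(intersect, contact_sets)
  always_contact <- sort(intersect(all_ids, in_all))
  always_free <- sort(setdiff(all_ids, in_any))
  conditional <- sort(setdiff(all_ids, c(always_contact, always_free)))
  if (length(conditional) == 0) {
    message("classify_points: no conditional point; all conformers share one shape")
  }
  structure(
    list(
      lattice = lattice, always_free = always_free,
      always_contact = always_contact, conditional = conditional,
      ccr_keys = NULL
    ),
    class = "pocket_points"
  )
}

#' @export
print.pocket_points <- function(x, ...) {
  cat(
    "<pocket_points>", nrow(x$lattice$points), "points:",
    length(x$always_free), "always-free,",
    length(x$always_contact), "always-contact,",
    length(x$conditional), "conditional\n"
  )
  invisible(x)
}

#' Identify conditional contact residues (CCRs)
#'
#' Conditional contact residues are the second-layer residues for which at
#' least one rotamer touches at least one conditional point - the residues
#' actually able to modulate the pocket shape.
#'
#' @param slr_keys Second-layer residue keys.
#' @param per_residue_conditional Named list: residue key -> integer vector
#'   of conditional point ids touched by any of its rotamers.
#' @return Sorted character vector of CCR keys.
#' @export
identify_ccrs <- function(slr_keys, per_residue_conditional) {
  hit <- vapply(
    slr_keys,
    function(k) length(per_residue_conditional[[k]]) > 0,
    logical(1)
  )
  sort(slr_keys[hit])
}

#' Export lattice points as a table
#'
#' @param points A `pocket_points` object.
#' @return Tibble (id, i, j, k, x, y, z, class) where class is "free",
#'   "conditional" or "contact".
#' @export
points_table <- function(points) {
  tbl <- points$lattice$points
  cls <- rep("free", nrow(tbl))
  cls[tbl$id %in% points$always_contact] <- "contact"
  cls[tbl$id %in% points$conditional] <- "conditional"
  dplyr::mutate(tbl, class = cls)
}

#' Write lattice points as PDB pseudo-atoms
#'
#' One HETATM per point; the B-factor encodes the class (0 free,
#' 1 conditional, 2 contact), convenient for molecular viewers.
#'
#' @param points A `pocket_points`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_points_pdb <- function(points, path) {
  tbl <- points_table(points)
  b <- c(free = 0, conditional = 1, contact = 2)[tbl$class]
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(tbl[, c("x", "y", "z")]))),
    type = rep("HETATM", nrow(tbl)),
    resno = tbl$id, resid = rep("PNT", nrow(tbl)),
    chain = rep("P", nrow(tbl)),
    eleno = tbl$id, elety = rep("C", nrow(tbl)),
    o = rep(1, nrow(tbl)), b = as.numeric(b)
  )
  invisible(path)
}
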