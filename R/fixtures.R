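# Deterministic synthetic toy systems: a rigid wall of alanine
# pseudo-residues forming a concave cylindrical pocket, chi-bearing
# flexible residues set into the wall at mid-height, and small rigid
# carbon-cluster ligands inside the pocket. Real amino-acid geometry is
# used throughout so the rotamer machinery runs unmodified; sequence and
# fold realism are explicit non-goals.

# Canonical residue backbone in a local frame: CA at the origin, N and C
# in the xy-plane at the ideal 111 deg angle, O and CB from ideal
# internal coordinates (L chirality).
local_residue <- function() {
  th <- 55.5 * pi / 180
  n <- 1.46 * c(cos(th), sin(th), 0)
  ca <- c(0, 0, 0)
  cc <- 1.52 * c(cos(th), -sin(th), 0)
  o <- place_atom(n, ca, cc, 1.23, 120.5, 0)
  cb <- build_cb(n, ca, cc)
  list(N = n, CA = ca, C = cc, O = o, CB = cb)
}

# Minimal rotation mapping unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- unit(a)
  b <- unit(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis orthogonal to a
    axis <- unit(cross3(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(rot_about(axis, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

rot_about <- function(axis, angle) {
  u <- unit(axis)
  c_ <- cos(angle)
  s <- sin(angle)
  outer(u, u) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3) * s
}

atom_rows <- function(pos_list, chain, resno, resid, radii = vdw_radius_table()) {
  elety <- names(pos_list)
  element <- substr(gsub("[0-9]", "", elety), 1, 1)
  xyz <- do.call(rbind, pos_list)
  tibble::tibble(
    chain = chain, resno = as.integer(resno), icode = "", resid = resid,
    elety = elety, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw = assign_vdw(element, elety, radii),
    is_backbone = elety %in% BACKBONE_ATOMS,
    res_key = res_key(chain, resno)
  )
}

# One residue at `ca`, oriented by a full deterministic frame: C-beta
# along `cb_dir`, backbone N->C axis along `axis_dir` (orthogonalised
# against cb_dir), optionally spun about cb_dir. Controlling both axes
# keeps wall residues flat in their ring plane.
place_rigid_residue <- function(ca, cb_dir, chain, resno, resid = "ALA",
                                spin = 0, axis_dir = NULL) {
  loc <- local_residue()
  e1 <- unit(loc$CB)
  bb <- loc$C - loc$N
  e2 <- unit(bb - sum(bb * e1) * e1)
  e3 <- cross3(e1, e2)
  f1 <- unit(cb_dir)
  if (is.null(axis_dir)) {
    axis_dir <- if (abs(f1[3]) < 0.9) cross3(f1, c(0, 0, 1)) else c(1, 0, 0)
  }
  f2 <- unit(axis_dir - sum(axis_dir * f1) * f1)
  f3 <- cross3(f1, f2)
  r <- rot_about(f1, spin) %*% (cbind(f1, f2, f3) %*% t(cbind(e1, e2, e3)))
  pos <- lapply(loc, function(v) ca + drop(r %*% v))
  if (resid == "GLY") pos$CB <- NULL
  atom_rows(pos, chain, resno, resid)
}

#' Toy-system specification
#'
#' @param n_flexible Number of flexible (chi-bearing) residues on the
#'   pocket rim ring (3-8 are sensible; default 4).
#' @param rotamers_per_residue Rotamers per residue type in the mini
#'   library (2-4; default 4, of which the fourth is a sub-well variant
#'   of the first).
#' @param n_ligands Number of toy ligands / holo structures (1-3).
#' @param flexible_type Residue type of the flexible residues.
#' @param pocket_radius Radius (Angstrom) of the flexible-residue C-alpha
#'   ring; the rigid wall stands 3 Angstrom further out.
#' @param pocket_depth Cavity depth in Angstrom.
#' @param seed Integer seed; the same spec + seed is bit-reproducible.
#' @param flex_tilt Upward tilt of the flexible C-beta directions
#'   (z component added to the inward unit vector).
#' @param flex_spin Spin of the flexible backbones about their C-beta
#'   axis, radians.
#' @param pair_angle Angular gap (degrees) within a close pair of
#'   flexible residues when `n_flexible >= 4`; close pairs make some
#'   rotamer pairs clash so the interaction graph is non-trivial.
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(n_flexible = 4, rotamers_per_residue = 4, n_ligands = 2,
                     flexible_type = "LEU", pocket_radius = 8.0,
                     pocket_depth = 8.0, seed = 1,
                     flex_tilt = 0.25, flex_spin = 0, pair_angle = 50) {
  stopifnot(
    n_flexible >= 1, rotamers_per_residue >= 1, n_ligands >= 1,
    pocket_radius > 5, pocket_depth > 5
  )
  structure(
    list(
      n_flexible = n_flexible, rotamers_per_residue = rotamers_per_residue,
      n_ligands = n_ligands, flexible_type = flexible_type,
      pocket_radius = pocket_radius, pocket_depth = pocket_depth, seed = seed,
      flex_tilt = flex_tilt, flex_spin = flex_spin, pair_angle = pair_angle
    ),
    class = "toy_spec"
  )
}

#' Canonical mini-library rotamers for one residue type
#'
#' Rotamers 1-3 are the three staggered chi1 wells; further entries are
#' sub-well variants (chi2 + 1 degree, then chi1 + 3 degrees, then a
#' genuine chi2 well change), mimicking the near-duplicate entries real
#' backbone-independent libraries carry. At the default lattice
#' resolution the +1 degree variants typically yield bit-identical pocket
#' footprints, so deduplication has real work on toy systems.
#'
#' @param type Three-letter residue type with a chi topology.
#' @param n Number of rotamers (1-12).
#' @return Rotamer library tibble for one type.
#' @export
# Canonical chi sets for the mini library. Rotamers 1-3 are the three
# staggered chi1 wells; further rotamers are sub-well variants of them
# (chi2 + 1 degree, then chi1 + 3 degrees, then a genuine chi2 well
# change), as real backbone-independent libraries carry near-duplicate
# entries. At 1 A lattice / 0.5 A padding resolution the +1 degree
# variants typically produce bit-identical pocket footprints and the +3
# degree variants near-identical ones, so the pruning and merging stages
# have real work on the toy system.
canonical_rotamers <- function(type, n) {
  nchi <- chi_counts()[[type]]
  if (is.null(nchi)) stop("no rotamers for residue type ", type)
  if (n > 12) stop("the mini library supports at most 12 rotamers per type")
  wells1 <- c(-60, 180, 65)
  wells2 <- c(180, 65, -65)
  chis <- matrix(NA_real_, n, 4)
  for (r in seq_len(n)) {
    well <- (r - 1) %% 3 + 1
    v <- (r - 1) %/% 3
    chi <- c(wells1[well], wells2[1], 180, 175)[seq_len(nchi)]
    if (v == 1) {
      if (nchi >= 2) chi[2] <- chi[2] + 1 else chi[1] <- chi[1] + 2
    } else if (v == 2) {
      chi[1] <- chi[1] + 3
    } else if (v == 3) {
      if (nchi >= 2) chi[2] <- wells2[2] else chi[1] <- chi[1] + 8
    }
    chis[r, seq_len(nchi)] <- normalize_angle(chi)
  }
  tibble::tibble(
    res_name = type, rotamer_id = seq_len(n),
    chi1 = chis[, 1], chi2 = chis[, 2], chi3 = chis[, 3], chi4 = chis[, 4],
    probability = round(1 / n, 4)
  )
}

#' Generate a deterministic toy pocket system
#'
#' Builds a rigid deep-well pocket (floor plate plus stacked dense wall
#' rings of alanine residues), `n_flexible` chi-bearing residues on their
#' own mid-height ring with C-beta pointing into the cavity, a mini
#' rotamer library, and `n_ligands` small carbon-cluster ligands placed
#' inside the pocket. Each ligand is delivered on its own holo copy of
#' the scaffold; holo copies after the first are rigidly displaced so the
#' superposition stage has real work to do.
#'
#' @param spec A [toy_spec()].
#' @return List with `template` (apo `pocket_structure`), `holo` (list of
#'   ligand-bound `pocket_structure`, displaced frames), `library`
#'   (rotamer tibble), `flexible_keys`, and `spec`.
#' @export
make_toy_system <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  depth <- spec$pocket_depth
  flex_r <- spec$pocket_radius # CA radius of the flexible-residue ring
  wall_r <- spec$pocket_radius + 3 # CA radius of the rigid wall rings
  rows <- list()
  resno <- 0L
  add <- function(rowtbl) {
    rows[[length(rows) + 1L]] <<- rowtbl
  }
  # floor plate: square CA grid, C-beta up into the cavity
  zfloor <- -(depth + 1.8)
  gr <- seq(-wall_r - 2, wall_r + 2, by = 2.6)
  for (gx in gr) {
    for (gy in gr) {
      if (sqrt(gx^2 + gy^2) > wall_r + 2.5) next
      resno <- resno + 1L
      add(place_rigid_residue(c(gx, gy, zfloor), c(0, 0, 1), "W", resno))
    }
  }
  # dense wall rings from the floor up past the rim, C-beta outwards so
  # the cavity-facing surface is smooth backbone; the wall stands 3 A
  # outside the flexible ring so side chains have clearance in every
  # rotamer, and it rises well above the flexible ring so the cavity is a
  # deep well whose interior is buried along the diagonal scan lines
  n_wall <- as.integer(ceiling(2 * pi * wall_r / 2.4))
  ring_z <- seq(-depth + 1.2, depth / 2, by = 1.8)
  for (ring in seq_along(ring_z)) {
    for (s in seq_len(n_wall)) {
      phi <- 2 * pi * (s - 1) / n_wall + (ring - 1) * pi / n_wall
      inward <- c(-cos(phi), -sin(phi), 0)
      tangent <- c(-sin(phi), cos(phi), 0)
      ca <- c(wall_r * cos(phi), wall_r * sin(phi), ring_z[ring])
      resno <- resno + 1L
      add(place_rigid_residue(ca, -inward, "W", resno, axis_dir = tangent))
    }
  }
  # flexible residues on their own mid-height ring; for 4+ residues they
  # sit in close pairs (pair_angle apart) so that some rotamer pairs of a
  # pair genuinely clash, while 1-3 residues are spread out and
  # independent
  flex_keys <- character(0)
  flex_rows <- list()
  nf <- spec$n_flexible
  if (nf <= 3) {
    phis <- 2 * pi * (seq_len(nf) - 1) / max(nf, 2)
  } else {
    base <- 2 * pi * (ceiling(seq_len(nf) / 2) - 1) / ceiling(nf / 2)
    phis <- base + ((seq_len(nf) - 1) %% 2) * spec$pair_angle * pi / 180
  }
  flex_z <- -depth / 2 + 0.2
  for (f in seq_len(nf)) {
    phi <- phis[f]
    inward <- c(-cos(phi), -sin(phi), 0)
    tangent <- c(-sin(phi), cos(phi), 0)
    ca <- c(flex_r * cos(phi), flex_r * sin(phi), flex_z)
    dir <- unit(inward + c(0, 0, spec$flex_tilt))
    resno <- resno + 1L
    rr <- place_rigid_residue(
      ca, dir, "F", resno,
      resid = spec$flexible_type, spin = spec$flex_spin, axis_dir = tangent
    )
    flex_keys <- c(flex_keys, rr$res_key[1])
    flex_rows[[length(flex_rows) + 1L]] <- rr
  }
  atoms <- dplyr::bind_rows(c(rows, flex_rows)) |>
    dplyr::arrange(.data$chain, .data$resno)
  # the template carries the flexible side chains in their first library
  # rotamer (an apo-form conformation); build them now
  lib <- canonical_rotamers(spec$flexible_type, spec$rotamers_per_residue)
  for (k in flex_keys) {
    ratoms <- atoms[atoms$res_key == k, ]
    sc <- apply_rotamer(ratoms, spec$flexible_type, chi_of(lib[1, ]))
    atoms <- dplyr::bind_rows(atoms[!(atoms$res_key == k & !atoms$is_backbone), ], sc) |>
      dplyr::arrange(.data$chain, .data$resno)
  }
  empty_lig <- atoms[0, ]
  empty_lig$ligand_id <- character(0)
  template <- new_structure(atoms, empty_lig, source = "toy_template")

  # ligands: compact carbon clusters inside the cavity, lightly jittered
  holo <- vector("list", spec$n_ligands)
  for (j in seq_len(spec$n_ligands)) {
    base_z <- -depth + 1.5 + (j - 1) * 1.2
    n_at <- 3 + (j %% 2)
    ang <- 2 * pi * seq_len(n_at) / n_at + j
    lx <- 1.4 * cos(ang) + stats::runif(n_at, -0.05, 0.05)
    ly <- 1.4 * sin(ang) + stats::runif(n_at, -0.05, 0.05)
    lz <- base_z + seq(0, 1.6, length.out = n_at) + stats::runif(n_at, -0.05, 0.05)
    lig <- tibble::tibble(
      chain = "L", resno = 900L + j, icode = "", resid = sprintf("LG%d", j),
      elety = paste0("C", seq_len(n_at)), element = "C",
      x = lx, y = ly, z = lz,
      vdw = assign_vdw(rep("C", n_at)),
      is_backbone = FALSE,
      res_key = res_key("L", 900L + j),
      ligand_id = sprintf("LG%d_L:%d", j, 900L + j)
    )
    h <- new_structure(atoms, lig, source = sprintf("toy_holo%d", j))
    if (j > 1) {
      # rigid displacement: recoverable by backbone superposition
      rot <- rot_about(c(1, 0.4, 0.3), 0.4 * (j - 1))
      shift <- c(3, -2, 1.5) * (j - 1)
      tf <- function(df) {
        if (nrow(df) == 0) return(df)
        xyz <- t(rot %*% t(coords(df))) + matrix(shift, nrow(df), 3, byrow = TRUE)
        df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
        df
      }
      h$atoms <- tf(h$atoms)
      h$ligands <- tf(h$ligands)
    }
    holo[[j]] <- h
  }
  list(
    template = template, holo = holo, library = lib,
    flexible_keys = sort(flex_keys), spec = spec
  )
}

#' Planted bit-string clusters with ground truth
#'
#' Draws `k` random centre bit strings with pairwise Hamming separation
#' of at least `4 * noise_bits` (at least 1), then generates members by
#' flipping exactly `noise_bits` random positions of their centre. Every
#' centre receives at least one member. Supports clustering-recovery
#' tests where the truth is known by construction.
#'
#' @param n_strings,n_bits,k,noise_bits Sizes; `k <= n_strings`.
#' @param seed Integer seed.
#' @param max_tries Redraw attempts before declaring the separation
#'   constraint unsatisfiable.
#' @return List with `bits` (logical matrix), `labels` (integer truth),
#'   `centers` (logical matrix).
#' @export
make_planted_clusters <- function(n_strings = 200, n_bits = 120, k = 8,
                                  noise_bits = 3, seed = 1, max_tries = 200) {
  stopifnot(k <= n_strings, noise_bits >= 0)
  set.seed(seed)
  min_sep <- max(1, 4 * noise_bits)
  centers <- matrix(stats::runif(k * n_bits) < 0.5, k, n_bits)
  for (tries in seq_len(max_tries)) {
    if (k == 1) break
    dh <- as.matrix(stats::dist(centers * 1L, method = "manhattan"))
    diag(dh) <- Inf
    bad <- which(apply(dh, 1, min) < min_sep)
    if (length(bad) == 0) break
    centers[bad[1], ] <- stats::runif(n_bits) < 0.5
    if (tries == max_tries) {
      stop("could not draw ", k, " centres with pairwise Hamming separation >= ", min_sep)
    }
  }
  labels <- c(seq_len(k), sample(seq_len(k), n_strings - k, replace = TRUE))
  bits <- centers[labels, , drop = FALSE]
  if (noise_bits > 0) {
    for (s in seq_len(n_strings)) {
      flip <- sample(n_bits, noise_bits)
      bits[s, flip] <- !bits[s, flip]
    }
  }
  list(bits = bits, labels = labels, centers = centers)
}

#' Materialise a toy system on disk
#'
#' Writes the template and holo structures as PDB files and the mini
#' rotamer library as TSV into a directory.
#'
#' @param spec A [toy_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_toy_system <- function(spec = toy_spec(), dir) {
  sys <- make_toy_system(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(template = file.path(dir, "template.pdb"))
  write_structure(sys$template, paths$template)
  for (j in seq_along(sys$holo)) {
    p <- file.path(dir, sprintf("holo%d.pdb", j))
    write_structure(sys$holo[[j]], p)
    paths[[sprintf("holo%d", j)]] <- p
  }
  paths$library <- file.path(dir, "rotamer_library.tsv")
  write_rotamer_library(sys$library, paths$library)
  invisible(paths)
}
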