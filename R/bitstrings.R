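#' Point-contact parameters
#'
#' A lattice point contacts an atom when their distance falls below the
#' atom's van der Waals radius plus the contact padding distance (CPD).
#' The point is treated as a zero-radius probe; the padding absorbs the
#' finite lattice resolution.
#'
#' @param cpd Contact padding distance in Angstrom (default 0.5).
#' @param radii Radius table, see [vdw_radius_table()].
#' @return List with `cpd` and `radii`.
#' @export
contact_params <- function(cpd = 0.5, radii = vdw_radius_table()) {
  stopifnot(cpd >= 0)
  list(cpd = cpd, radii = radii)
}

#' Point-atom contact test
#'
#' `TRUE` iff `dist(point, atom) < vdw(atom) + CPD`.
#'
#' @param point Numeric length-3 coordinate (Angstrom).
#' @param atom Single-row atom tibble (or list) with `x`, `y`, `z`, `vdw`.
#' @param params See [contact_params()].
#' @return Logical scalar.
#' @export
point_contact <- function(point, atom, params = contact_params()) {
  d <- sqrt((point[1] - atom$x)^2 + (point[2] - atom$y)^2 + (point[3] - atom$z)^2)
  d < atom$vdw + params$cpd
}

# Vectorised: which of the points (n x 3 matrix) contact any atom in the
# tibble. Returns a logical vector over points.
points_in_contact <- function(pts, atoms, params = contact_params()) {
  out <- rep(FALSE, nrow(pts))
  if (nrow(atoms) == 0) return(out)
  ax <- coords(atoms)
  for (t in seq_len(nrow(ax))) {
    r <- atoms$vdw[t] + params$cpd
    d2 <- (pts[, 1] - ax[t, 1])^2 + (pts[, 2] - ax[t, 2])^2 + (pts[, 3] - ax[t, 3])^2
    out <- out | (d2 < r^2)
  }
  out
}

#' Per-rotamer lattice contact sets
#'
#' For every flexible residue and every surviving rotamer, the ids of the
#' lattice points its side-chain atoms contact. All conformer-level
#' encoding reduces to unions of these sets, so the per-atom work is done
#' once per rotamer rather than once per conformer.
#'
#' @param placements A `rotamer_placements`.
#' @param lattice A `pocket_lattice`.
#' @param params See [contact_params()].
#' @return Named list: residue key -> list (per surviving rotamer) of
#'   integer point-id vectors.
#' @export
rotamer_contact_sets <- function(placements, lattice, params = contact_params()) {
  pts <- lattice_coords(lattice)
  ids <- lattice$points$id
  lapply(
    stats::setNames(placements$residues, placements$residues),
    function(k) {
      lapply(placements$placements[[k]], function(pl) {
        ids[points_in_contact(pts, pl, params)]
      })
    }
  )
}

# Contacted point-id set of one conformer (named assignment row).
conformer_contact_set <- function(assignment, contact_sets) {
  sets <- lapply(names(contact_sets), function(k) contact_sets[[k]][[assignment[[k]]]])
  sort(unique(unlist(sets)))
}

#' Contact sets of all conformers
#'
#' @param conformers Conformer matrix from [enumerate_conformers()].
#' @param contact_sets Output of [rotamer_contact_sets()].
#' @return List (per conformer) of contacted point-id vectors.
#' @export
conformer_contact_sets <- function(conformers, contact_sets) {
  keys <- colnames(conformers)
  lapply(seq_len(nrow(conformers)), function(t) {
    sets <- lapply(keys, function(k) contact_sets[[k]][[conformers[t, k]]])
    sort(unique(unlist(sets)))
  })
}

#' Encode one conformer as a shape bit string
#'
#' Bit i is set iff conditional point i is contacted by at least one
#' side-chain atom of the conformer. The bit order is the (immutable)
#' order of the conditional points.
#'
#' @param assignment Named integer vector (residue key -> surviving
#'   rotamer index) or one row of the conformer matrix.
#' @param contact_sets Output of [rotamer_contact_sets()].
#' @param points A `pocket_points`.
#' @return Logical vector of length `length(points$conditional)`.
#' @export
encode <- function(assignment, contact_sets, points) {
  touched <- conformer_contact_set(as.list(assignment), contact_sets)
  points$conditional %in% touched
}

#' Encode all conformers as a bit matrix
#'
#' @param conformers Conformer matrix.
#' @param contact_sets Output of [rotamer_contact_sets()].
#' @param points A `pocket_points`.
#' @return Logical matrix (conformers x conditional points).
#' @export
encode_conformers <- function(conformers, contact_sets, points) {
  cond <- points$conditional
  keys <- colnames(conformers)
  # pre-translate each rotamer's contacted ids to conditional bit positions
  bitpos <- lapply(contact_sets[keys], function(per_res) {
    lapply(per_res, function(ids) which(cond %in% ids))
  })
  bits <- matrix(FALSE, nrow(conformers), length(cond))
  for (t in seq_len(nrow(conformers))) {
    for (k in seq_along(keys)) {
      bits[t, bitpos[[k]][[conformers[t, k]]]] <- TRUE
    }
  }
  bits
}

new_shape_strings <- function(bits, conformers, point_ids) {
  structure(
    list(
      bits = bits, conformers = conformers, point_ids = point_ids,
      string_id = seq_len(nrow(bits))
    ),
    class = "shape_strings"
  )
}

#' @export
print.shape_strings <- function(x, ...) {
  cat(
    "<shape_strings>", nrow(x$bits), "unique strings of",
    ncol(x$bits), "bits,", sum(lengths(x$conformers)), "conformers\n"
  )
  invisible(x)
}

#' Deduplicate conformer bit strings
#'
#' Hashes the bit patterns and keeps one entry per distinct pattern,
#' merging the conformer ids so no conformer is lost: the group sizes sum
#' to the input count. Unique strings are ordered by first occurrence.
#'
#' @param bits Logical matrix (conformers x bits) from
#'   [encode_conformers()].
#' @param conformer_ids Integer ids of the rows (default `1:nrow`).
#' @param point_ids Conditional point ids defining the bit order.
#' @return A `shape_strings` collection: `bits` (unique patterns),
#'   `conformers` (list of id vectors), `point_ids`, `string_id`.
#' @export
deduplicate <- function(bits, conformer_ids = seq_len(nrow(bits)),
                        point_ids = seq_len(ncol(bits))) {
  if (length(conformer_ids) != nrow(bits)) stop("one conformer id per row required")
  keys <- bits_to_hex(bits)
  first <- !duplicated(keys)
  uniq_keys <- keys[first]
  groups <- split(conformer_ids, factor(keys, levels = uniq_keys))
  new_shape_strings(
    bits = bits[first, , drop = FALSE],
    conformers = unname(lapply(groups, function(g) sort(unname(g)))),
    point_ids = point_ids
  )
}

#' Hamming distance between two bit vectors
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return Integer number of differing positions.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) stop("bit strings differ in length")
  sum(as.logical(a) != as.logical(b))
}

# Canonical string order used by merge_similar: descending conformer
# count, ties by bit pattern treated as a binary number (lexicographic).
canonical_order <- function(strings) {
  n_conf <- lengths(strings$conformers)
  pattern <- apply(strings$bits, 1, function(r) paste(as.integer(r), collapse = ""))
  order(-n_conf, pattern)
}

#' Merge near-identical bit strings
#'
#' Greedy single-pass merge: strings are visited in a canonical order
#' (descending conformer count, ties by bit pattern); each joins the first
#' existing group whose *founding* string lies at Hamming distance
#' strictly below `threshold_bits`, else founds a new group. Group
#' representatives are the founding strings and conformer ids are pooled.
#' With `method = "single_linkage"` the merge is instead the transitive
#' closure (connected components of the below-threshold graph), with the
#' canonical-first member as representative.
#'
#' @param strings A `shape_strings` collection (deduplicated).
#' @param threshold_bits Strict Hamming threshold (default 5: "differ by
#'   fewer than 5 bits"). 0 merges nothing.
#' @param method "greedy" (default) or "single_linkage".
#' @return A merged `shape_strings`; attribute `members` lists, per group,
#'   the original string ids it absorbed.
#' @export
merge_similar <- function(strings, threshold_bits = 5, method = c("greedy", "single_linkage")) {
  method <- match.arg(method)
  if (threshold_bits < 0) stop("threshold_bits must be >= 0")
  ord <- canonical_order(strings)
  bits <- strings$bits
  if (method == "greedy") {
    rep_idx <- integer(0)
    member_of <- integer(nrow(bits))
    for (s in ord) {
      joined <- FALSE
      if (threshold_bits > 0 && length(rep_idx) > 0) {
        reps <- bits[rep_idx, , drop = FALSE]
        h <- rowSums(reps != matrix(bits[s, ], nrow(reps), ncol(bits), byrow = TRUE))
        hit <- which(h < threshold_bits)
        if (length(hit) > 0) {
          member_of[s] <- hit[1]
          joined <- TRUE
        }
      }
      if (!joined) {
        rep_idx <- c(rep_idx, s)
        member_of[s] <- length(rep_idx)
      }
    }
  } else {
    adj <- which(
      as.matrix(stats::dist(bits * 1L, method = "manhattan")) < threshold_bits,
      arr.ind = TRUE
    )
    g <- igraph::graph_from_data_frame(
      as.data.frame(adj[adj[, 1] < adj[, 2], , drop = FALSE]),
      directed = FALSE, vertices = data.frame(name = seq_len(nrow(bits)))
    )
    memb <- igraph::components(g)$membership
    # representative: canonical-first member of each component
    pos_in_ord <- match(seq_len(nrow(bits)), ord)
    rep_idx <- vapply(
      split(seq_len(nrow(bits)), memb),
      function(m) m[which.min(pos_in_ord[m])], integer(1)
    )
    comp_of <- as.integer(memb)
    grp <- match(comp_of, comp_of[rep_idx])
    member_of <- grp
    # reorder groups by canonical order of their representatives
    rord <- order(pos_in_ord[rep_idx])
    rep_idx <- rep_idx[rord]
    member_of <- match(member_of, rord)
  }
  groups <- unname(split(seq_len(nrow(bits)), member_of))
  out <- new_shape_strings(
    bits = bits[rep_idx, , drop = FALSE],
    conformers = lapply(groups, function(m) {
      sort(unname(unique(unlist(strings$conformers[m]))))
    }),
    point_ids = strings$point_ids
  )
  attr(out, "members") <- lapply(groups, function(m) strings$string_id[m])
  out
}

#' Shape-fingerprint Tanimoto similarity
#'
#' `N_AB / (N_A + N_B - N_AB)` where `N_A`, `N_B` are the set-bit counts
#' and `N_AB` the count of commonly set bits: the proportion of shared
#' bits, i.e. the relative volume overlap of the two pocket shapes at the
#' lattice resolution.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return Similarity in `[0, 1]`. Two all-zero strings are identical
#'   empty shapes: similarity 1 with a warning.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("bit strings differ in length")
  a <- as.logical(a)
  b <- as.logical(b)
  na <- sum(a)
  nb <- sum(b)
  nab <- sum(a & b)
  if (na + nb == 0) {
    warning("both bit strings are all-zero; returning similarity 1")
    return(1)
  }
  nab / (na + nb - nab)
}

#' Pairwise shape dissimilarity matrix
#'
#' Symmetric matrix of `1 - SFT` (shape-fingerprint Tanimoto) values with
#' zero diagonal, the clustering input.
#'
#' @param strings A `shape_strings` collection or a logical bit matrix.
#' @return Numeric matrix with string ids as dimnames.
#' @export
dissimilarity_matrix <- function(strings) {
  bits <- if (inherits(strings, "shape_strings")) strings$bits else strings
  if (nrow(bits) < 2) stop("need at least 2 strings")
  m <- bits * 1
  nab <- tcrossprod(m)
  n <- rowSums(m)
  denom <- outer(n, n, "+") - nab
  sim <- ifelse(denom == 0, 1, nab / ifelse(denom == 0, 1, denom))
  d <- 1 - sim
  diag(d) <- 0
  ids <- if (inherits(strings, "shape_strings")) strings$string_id else seq_len(nrow(bits))
  dimnames(d) <- list(as.character(ids), as.character(ids))
  d
}

# Hex serialisation of bit rows (MSB-first within each 4-bit nibble).
bits_to_hex <- function(bits) {
  apply(bits, 1, function(r) {
    pad <- (4 - length(r) %% 4) %% 4
    r <- c(r, rep(FALSE, pad))
    nib <- matrix(as.integer(r), nrow = 4)
    paste(sprintf("%x", as.integer(8 * nib[1, ] + 4 * nib[2, ] + 2 * nib[3, ] + nib[4, ])), collapse = "")
  })
}

#' @export
#' @method as_tibble shape_strings
#' @importFrom tibble as_tibble
as_tibble.shape_strings <- function(x, ...) {
  tibble::tibble(
    string_id = x$string_id,
    bits_hex = bits_to_hex(x$bits),
    popcount = rowSums(x$bits),
    n_conformers = lengths(x$conformers),
    representative_conformer = vapply(x$conformers, min, numeric(1))
  )
}
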