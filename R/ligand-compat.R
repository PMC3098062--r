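#' Encode a ligand volume on the pocket lattice
#'
#' Marks the lattice points lying within `vdw(atom) + CPD` of at least one
#' ligand heavy atom - the same contact rule used for pocket encoding, so
#' ligand and pocket shapes live on the same lattice and compare by bit
#' operations.
#'
#' @param ligand_atoms Atom tibble (`x`, `y`, `z`, `vdw`) of one ligand.
#' @param lattice A `pocket_lattice`.
#' @param params See [contact_params()].
#' @param ligand_id Identifier stored with the volume.
#' @return A `ligand_volume`: list with `ligand_id` and `point_ids`
#'   (sorted, possibly empty with a warning when the ligand misses the
#'   lattice).
#' @export
encode_ligand_volume <- function(ligand_atoms, lattice, params = contact_params(),
                                 ligand_id = ligand_atoms$ligand_id[1]) {
  pts <- lattice_coords(lattice)
  hit <- points_in_contact(pts, ligand_atoms, params)
  ids <- lattice$points$id[hit]
  if (length(ids) == 0) {
    warning("ligand ", ligand_id, " occupies no lattice point (outside the pocket box?)")
  }
  structure(
    list(ligand_id = ligand_id, point_ids = sort(ids)),
    class = "ligand_volume"
  )
}

#' Open pocket volume of one conformer
#'
#' The point set a conformer leaves open: all always-free points plus the
#' conditional points whose bit is off in the conformer's shape string.
#'
#' @param points A `pocket_points`.
#' @param bits Logical bit vector over the conditional points.
#' @return Sorted integer vector of open point ids.
#' @export
pocket_open_points <- function(points, bits) {
  if (length(bits) != length(points$conditional)) {
    stop("bit vector length does not match the conditional point count")
  }
  sort(c(points$always_free, points$conditional[!as.logical(bits)]))
}

#' Ligand-pocket shape incompatibility
#'
#' The relative complement L \\ P: the number of ligand-occupied lattice
#' points that fall outside the conformer's open pocket volume, i.e. the
#' ligand volume sticking out of (or into the walls of) the pocket.
#' Multiply by spacing cubed for cubic Angstrom.
#'
#' @param ligand A `ligand_volume`.
#' @param pocket_open Open point ids, see [pocket_open_points()].
#' @return Integer count.
#' @export
incompatibility <- function(ligand, pocket_open) {
  length(setdiff(ligand$point_ids, pocket_open))
}

#' Incompatibility profile of all shapes against all ligands
#'
#' Computes the full strings-by-ligands matrix of shape incompatibilities
#' by bit operations: a ligand point always counts against the score when
#' it sits on an always-contact point (inside the wall in every
#' conformer), plus one for every set bit at a ligand-occupied
#' conditional point.
#'
#' @param ligands List of `ligand_volume` objects.
#' @param strings A `shape_strings` collection.
#' @param points A `pocket_points`.
#' @return Integer matrix (strings x ligands) with string ids as rownames
#'   and ligand ids as colnames.
#' @export
incompatibility_profile <- function(ligands, strings, points) {
  if (inherits(ligands, "ligand_volume")) ligands <- list(ligands)
  out <- matrix(
    0L, nrow(strings$bits), length(ligands),
    dimnames = list(
      as.character(strings$string_id),
      vapply(ligands, function(l) l$ligand_id, character(1))
    )
  )
  for (j in seq_along(ligands)) {
    l <- ligands[[j]]
    base <- length(intersect(l$point_ids, points$always_contact)) +
      length(setdiff(l$point_ids, points$lattice$points$id))
    cond_idx <- which(points$conditional %in% l$point_ids)
    out[, j] <- base + as.integer(rowSums(strings$bits[, cond_idx, drop = FALSE]))
  }
  out
}

#' Heat map of an incompatibility profile
#'
#' @param profile Matrix from [incompatibility_profile()].
#' @param model Optional `shape_cluster_model`; when given, rows are
#'   ordered by cluster membership.
#' @return A ggplot object.
#' @export
plot_incompatibility <- function(profile, model = NULL) {
  ord <- rownames(profile)
  if (!is.null(model)) {
    td <- tidy(model)
    ord <- td$string_id[order(td$cluster)]
  }
  df <- as.data.frame(as.table(profile))
  names(df) <- c("string_id", "ligand", "incompatibility")
  df$string_id <- factor(df$string_id, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$ligand, .data$string_id, fill = .data$incompatibility)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "darkred", high = "white") +
    ggplot2::labs(
      y = "pocket shape (cluster order)", x = "ligand",
      fill = "L \\ P points", title = "Ligand-pocket shape incompatibility"
    ) +
    ggplot2::theme_minimal()
}
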