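#' Build the residue interaction graph
#'
#' Nodes are the flexible residues; an edge joins two residues when at
#' least one of their rotamer pairs clashes. Each edge stores the full
#' boolean compatibility matrix over surviving rotamer indices, so the
#' subsequent search never re-tests atom pairs.
#'
#' @param placements A `rotamer_placements` from [prefilter_rotamers()].
#' @param params See [clash_params()]; defaults to the parameters the
#'   placements were built with.
#' @return An `interaction_graph`: list with `residues` (sorted keys),
#'   `n_rot` (named integer), `edges` (list of `list(u, v, compat)` with
#'   `compat[i, j]` TRUE when rotamer i of u and j of v are jointly
#'   placeable).
#' @export
build_interaction_graph <- function(placements, params = placements$params) {
  keys <- placements$residues
  n_rot <- vapply(placements$placements, length, integer(1))
  edges <- list()
  if (length(keys) >= 2) {
    for (a in seq_len(length(keys) - 1)) {
      for (b in (a + 1):length(keys)) {
        pa <- placements$placements[[keys[a]]]
        pb <- placements$placements[[keys[b]]]
        compat <- matrix(TRUE, length(pa), length(pb))
        for (i in seq_along(pa)) {
          for (j in seq_along(pb)) {
            if (clash_any(
              coords(pa[[i]]), pa[[i]]$vdw,
              coords(pb[[j]]), pb[[j]]$vdw, params$ctd
            )) {
              compat[i, j] <- FALSE
            }
          }
        }
        if (!all(compat)) {
          edges[[paste(keys[a], keys[b], sep = "||")]] <-
            list(u = keys[a], v = keys[b], compat = compat)
        }
      }
    }
  }
  structure(
    list(residues = keys, n_rot = stats::setNames(n_rot, keys), edges = edges),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(
    "<interaction_graph>", length(x$residues), "residues,",
    length(x$edges), "constrained pair(s)\n"
  )
  invisible(x)
}

# Connected components of the interaction graph, each a sorted key vector;
# components ordered by their smallest member key.
graph_components <- function(graph) {
  if (length(graph$edges) == 0) {
    comps <- as.list(graph$residues)
  } else {
    el <- do.call(rbind, lapply(graph$edges, function(e) c(e$u, e$v)))
    g <- igraph::graph_from_data_frame(
      as.data.frame(el),
      directed = FALSE,
      vertices = data.frame(name = graph$residues)
    )
    memb <- igraph::components(g)$membership
    comps <- split(names(memb), memb)
    comps <- lapply(comps, sort)
  }
  comps[order(vapply(comps, function(c) c[1], character(1)))]
}

# Backtracking with forward checking over one component. Residues are
# processed in sorted key order and rotamer indices in library order, so
# the solution sequence is deterministic. `collect = FALSE` only counts.
solve_component <- function(graph, comp, collect = TRUE) {
  comp <- sort(comp)
  m <- length(comp)
  n_rot <- graph$n_rot[comp]
  # constraint lookup: compat[[a]][[b]] for a < b positions within comp
  compat <- vector("list", m)
  for (a in seq_len(m)) compat[[a]] <- vector("list", m)
  for (e in graph$edges) {
    a <- match(e$u, comp)
    b <- match(e$v, comp)
    if (is.na(a) || is.na(b)) next
    if (a < b) compat[[a]][[b]] <- e$compat else compat[[b]][[a]] <- t(e$compat)
  }
  sols <- list()
  count <- 0
  assign <- integer(m)
  domains <- lapply(n_rot, seq_len)
  recurse <- function(pos, domains) {
    if (pos > m) {
      count <<- count + 1
      if (collect) sols[[count]] <<- assign
      return(invisible(NULL))
    }
    for (r in domains[[pos]]) {
      assign[pos] <<- r
      new_domains <- domains
      ok <- TRUE
      if (pos < m) {
        for (q in (pos + 1):m) {
          cm <- compat[[pos]][[q]]
          if (is.null(cm)) next
          new_domains[[q]] <- new_domains[[q]][cm[r, new_domains[[q]]]]
          if (length(new_domains[[q]]) == 0) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) recurse(pos + 1, new_domains)
    }
    invisible(NULL)
  }
  recurse(1, domains)
  if (count == 0) {
    stop(
      "no clash-free rotamer combination for component {",
      paste(comp, collapse = ", "), "}"
    )
  }
  if (collect) {
    list(residues = comp, solutions = do.call(rbind, sols), count = count)
  } else {
    list(residues = comp, solutions = NULL, count = count)
  }
}

#' Enumerate all clash-free conformers
#'
#' Exhaustively enumerates every complete assignment of one surviving
#' rotamer per flexible residue such that all edge-constrained pairs are
#' compatible. The graph is decomposed into connected components; each is
#' solved by backtracking with forward-checking pruning (which only prunes
#' provably dead branches, so enumeration stays exhaustive), and the full
#' set is the Cartesian product of the per-component solutions. Output
#' order is deterministic: residues sorted by key, rotamers by library
#' order, earlier components varying slowest.
#'
#' @param graph An `interaction_graph`.
#' @return Integer matrix (conformers x residues); entries are indices
#'   into the surviving rotamer list of each residue (column names are the
#'   sorted residue keys). Row order defines the conformer ids 1..n.
#' @export
enumerate_conformers <- function(graph) {
  comps <- graph_components(graph)
  solved <- lapply(comps, function(c) solve_component(graph, c, collect = TRUE))
  counts <- vapply(solved, function(s) s$count, numeric(1))
  total <- prod(counts)
  if (total > 5e7) stop("refusing to materialise ", total, " conformers")
  m <- length(comps)
  # mixed-radix expansion: component 1 most significant
  out <- matrix(0L, nrow = total, ncol = length(graph$residues))
  colnames(out) <- graph$residues
  t0 <- seq_len(total) - 1L
  rad <- c(rev(cumprod(rev(counts)))[-1], 1)
  for (j in seq_len(m)) {
    idx <- (t0 %/% rad[j]) %% counts[j] + 1L
    out[, solved[[j]]$residues] <- solved[[j]]$solutions[idx, , drop = FALSE]
  }
  out
}

#' Count clash-free conformers without materialising them
#'
#' Per-component solution counts multiplied together; equals
#' `nrow(enumerate_conformers(graph))`.
#'
#' @param graph An `interaction_graph`.
#' @return Numeric count (may exceed integer range).
#' @export
count_conformers <- function(graph) {
  comps <- graph_components(graph)
  prod(vapply(comps, function(c) solve_component(graph, c, collect = FALSE)$count, numeric(1)))
}

#' Conformer table
#'
#' @param conformers Conformer matrix from [enumerate_conformers()].
#' @param placements Optional `rotamer_placements`; when given, entries
#'   are translated from surviving-rotamer indices to library rotamer ids.
#' @return Tibble with `conformer_id` and one column per residue key.
#' @export
conformer_table <- function(conformers, placements = NULL) {
  tbl <- tibble::as_tibble(as.data.frame(conformers))
  names(tbl) <- colnames(conformers)
  if (!is.null(placements)) {
    for (k in names(tbl)) {
      tbl[[k]] <- placements$rotamer_ids[[k]][tbl[[k]]]
    }
  }
  dplyr::mutate(tbl, conformer_id = dplyr::row_number(), .before = 1)
}

#' Materialise one conformer as a structure
#'
#' Replaces the side chains of the flexible residues by the placement of
#' the assigned rotamers, yielding a full-atom structure writable as PDB.
#'
#' @param structure Original `pocket_structure`.
#' @param placements A `rotamer_placements`.
#' @param assignment One row of the conformer matrix (named integer
#'   vector: residue key -> surviving rotamer index).
#' @return A `pocket_structure`.
#' @export
build_conformer_structure <- function(structure, placements, assignment) {
  keys <- placements$residues
  keep <- structure$atoms[
    !(structure$atoms$res_key %in% keys) | structure$atoms$is_backbone,
  ]
  side <- purrr::map_dfr(keys, function(k) placements$placements[[k]][[assignment[[k]]]])
  atoms <- dplyr::bind_rows(keep, side) |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode)
  new_structure(atoms, structure$ligands, source = structure$source)
}
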