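# Independent oracles used to pin the semantics of the main operations.
# Each is coded directly from the definition, without reusing the package
# internals it checks.

# Exhaustive nested-loop enumeration over an interaction graph: every
# complete assignment, filtered by the per-edge compatibility matrices.
brute_force_enumerate <- function(graph) {
  keys <- sort(graph$residues)
  grid <- expand.grid(lapply(graph$n_rot[keys], seq_len))
  names(grid) <- keys
  keep <- rep(TRUE, nrow(grid))
  for (e in graph$edges) {
    keep <- keep & e$compat[cbind(grid[[e$u]], grid[[e$v]])]
  }
  m <- as.matrix(grid[keep, keys, drop = FALSE])
  rownames(m) <- NULL
  m
}

# Canonical row-set signature for comparing conformer matrices as sets.
conformer_set_signature <- function(m) {
  m <- m[, sort(colnames(m)), drop = FALSE]
  sort(apply(m, 1, paste, collapse = ","))
}

# Random small interaction-graph instance with known structure.
random_instance <- function(n_res = sample(2:6, 1), max_rot = 5, p_clash = 0.25) {
  keys <- sprintf("R:%d", seq_len(n_res))
  n_rot <- setNames(sample(seq_len(max_rot), n_res, replace = TRUE), keys)
  edges <- list()
  for (a in seq_len(n_res - 1)) {
    for (b in (a + 1):n_res) {
      if (runif(1) < 0.6) {
        compat <- matrix(runif(n_rot[a] * n_rot[b]) > p_clash, n_rot[a], n_rot[b])
        if (!all(compat)) {
          edges[[paste(keys[a], keys[b], sep = "||")]] <-
            list(u = keys[a], v = keys[b], compat = compat)
        }
      }
    }
  }
  structure(list(residues = keys, n_rot = n_rot, edges = edges),
    class = "interaction_graph"
  )
}

# Scalar Tanimoto straight from the definition.
oracle_tanimoto <- function(a, b) {
  na <- sum(a)
  nb <- sum(b)
  nab <- sum(a & b)
  if (na + nb == 0) return(1)
  nab / (na + nb - nab)
}

# Quadratic-scan greedy merge reference with the same canonical ordering
# rule (descending conformer count, ties by 0/1 pattern string).
oracle_merge <- function(bits, conf_counts, threshold) {
  patt <- apply(bits, 1, function(r) paste(as.integer(r), collapse = ""))
  ord <- order(-conf_counts, patt)
  reps <- integer(0)
  member <- integer(nrow(bits))
  for (s in ord) {
    hit <- 0L
    if (threshold > 0 && length(reps) > 0) {
      h <- colSums(t(bits[reps, , drop = FALSE]) != bits[s, ])
      cand <- which(h < threshold)
      if (length(cand) > 0) hit <- cand[1]
    }
    if (hit == 0L) {
      reps <- c(reps, s)
      hit <- length(reps)
    }
    member[s] <- hit
  }
  list(reps = reps, member = member)
}

# Brute-force pocket-lattice scan: triple loop over the bounding box
# applying the three retention tests literally.
oracle_lattice <- function(structure, ensemble, flr_keys, spacing = 1,
                           trim_cutoff = 6, cavity_min_dirs = 4,
                           cavity_range = 14) {
  site <- structure$atoms[structure$atoms$res_key %in% flr_keys, ]
  anchors <- rbind(
    as.matrix(site[, c("x", "y", "z")]),
    as.matrix(ensemble[, c("x", "y", "z")])
  )
  lo <- floor((apply(anchors, 2, min) - trim_cutoff) / spacing)
  hi <- ceiling((apply(anchors, 2, max) + trim_cutoff) / spacing)
  at <- structure$atoms
  tax <- t(as.matrix(at[, c("x", "y", "z")]))
  r2 <- at$vdw^2
  inside <- function(p) {
    any(colSums((tax - p)^2) < r2)
  }
  dirs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(1, -1, -1)
  )
  kept <- list()
  for (i in lo[1]:hi[1]) {
    for (j in lo[2]:hi[2]) {
      for (k in lo[3]:hi[3]) {
        p <- c(i, j, k) * spacing
        if (inside(p)) next
        if (min(colSums((t(anchors) - p)^2)) >= trim_cutoff^2) next
        nb <- 0
        for (d in seq_len(7)) {
          u <- dirs[d, ] * spacing
          ns <- floor(cavity_range / sqrt(sum(u^2)))
          bp <- any(vapply(seq_len(ns), function(s) inside(p + s * u), logical(1)))
          bn <- any(vapply(seq_len(ns), function(s) inside(p - s * u), logical(1)))
          if (bp && bn) nb <- nb + 1
        }
        if (nb >= cavity_min_dirs) kept[[length(kept) + 1]] <- c(i, j, k)
      }
    }
  }
  do.call(rbind, kept)
}
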