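#' Classical MDS embedding of a dissimilarity matrix
#'
#' Principal-coordinate analysis: double-centre the squared
#' dissimilarities, eigendecompose, return the top-`dims` coordinates
#' scaled by the square root of their eigenvalues (stats::cmdscale).
#' Axes with non-positive eigenvalues are zero-filled. Each axis sign is
#' fixed so that its largest-magnitude coordinate is positive, making the
#' embedding fully deterministic.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param dims Number of output dimensions (default 3).
#' @return Numeric matrix (n x dims), rownames from `d`, columns
#'   `PC1..PCdims`.
#' @export
mds_embed <- function(d, dims = 3) {
  n <- nrow(d)
  if (all(d == 0)) {
    warning("all dissimilarities are zero; returning a zero embedding")
    emb <- matrix(0, n, dims)
  } else {
    k <- min(dims, n - 1)
    pts <- stats::cmdscale(stats::as.dist(d), k = k)
    emb <- matrix(0, n, dims)
    emb[, seq_len(ncol(pts))] <- pts
    for (j in seq_len(dims)) {
      v <- emb[, j]
      if (any(v != 0) && v[which.max(abs(v))] < 0) emb[, j] <- -v
    }
  }
  dimnames(emb) <- list(rownames(d), paste0("PC", seq_len(dims)))
  emb
}

#' Partition shapes by k-medoids
#'
#' PAM (partitioning around medoids) on the dissimilarity matrix with the
#' deterministic BUILD initialisation, replacing the visual cluster-count
#' choice of an interactive MDS viewer. With `k = "auto"` the cluster
#' count maximising the average silhouette width over `k_range` is chosen
#' (ties to the smallest k).
#'
#' @param d Dissimilarity matrix.
#' @param k Integer cluster count, `"auto"`, or `n` for the trivial
#'   one-string-per-cluster partition.
#' @param k_range Candidate range for `"auto"` (default 2..15, capped at
#'   n-1).
#' @return Named integer vector of cluster labels (1..k) with attributes
#'   `k` and `avg_silhouette`.
#' @export
assign_clusters <- function(d, k = "auto", k_range = 2:15) {
  n <- nrow(d)
  ids <- rownames(d)
  if (identical(k, "auto")) {
    ks <- k_range[k_range >= 2 & k_range <= n - 1]
    if (length(ks) == 0) ks <- min(2, n - 1)
    sil <- vapply(ks, function(kk) {
      cluster::pam(stats::as.dist(d), k = kk, diss = TRUE)$silinfo$avg.width
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  if (k > n) stop("k = ", k, " exceeds the number of strings (", n, ")")
  if (k == n) {
    labels <- stats::setNames(seq_len(n), ids)
    attr(labels, "k") <- k
    attr(labels, "avg_silhouette") <- NA_real_
    return(labels)
  }
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
  labels <- stats::setNames(as.integer(fit$clustering), ids)
  attr(labels, "k") <- k
  attr(labels, "avg_silhouette") <- if (k >= 2) fit$silinfo$avg.width else NA_real_
  labels
}

#' Medoid of a cluster
#'
#' The member whose average dissimilarity to the other members is
#' minimal; ties are broken by the lowest string id (matrix order).
#'
#' @param d Dissimilarity matrix.
#' @param members Member ids (rownames of `d`) or indices.
#' @return The medoid id (character if `d` has rownames).
#' @export
find_medoid <- function(d, members) {
  if (length(members) == 0) stop("empty member set")
  if (is.character(members)) members <- match(members, rownames(d))
  if (anyNA(members)) stop("unknown member id")
  members <- sort(members)
  if (length(members) == 1) {
    return(if (!is.null(rownames(d))) rownames(d)[members] else members)
  }
  sub <- d[members, members, drop = FALSE]
  avg <- rowSums(sub) / (length(members) - 1)
  best <- members[which.min(avg)]
  if (!is.null(rownames(d))) rownames(d)[best] else best
}

#' Cluster pocket shapes and pick representatives
#'
#' Runs the MDS embedding, the k-medoids partition and the per-cluster
#' medoid selection on a shape dissimilarity matrix, returning a fitted
#' model object with [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()] methods.
#'
#' @param d Dissimilarity matrix (`1 - SFT`), see
#'   [dissimilarity_matrix()].
#' @param k Cluster count or `"auto"` (see [assign_clusters()]).
#' @param dims Embedding dimensions (default 3).
#' @param k_range Candidate k values for `"auto"`.
#' @return A `shape_cluster_model`: list with `labels`, `medoids` (named
#'   by cluster), `embedding`, `k`, `avg_silhouette`, `diss`.
#' @export
fit_shape_clusters <- function(d, k = "auto", dims = 3, k_range = 2:15) {
  if (is.null(rownames(d))) dimnames(d) <- list(seq_len(nrow(d)), seq_len(nrow(d)))
  labels <- assign_clusters(d, k = k, k_range = k_range)
  emb <- mds_embed(d, dims = dims)
  medoids <- vapply(
    sort(unique(labels)),
    function(cl) find_medoid(d, names(labels)[labels == cl]),
    character(1)
  )
  names(medoids) <- sort(unique(labels))
  structure(
    list(
      labels = labels, medoids = medoids, embedding = emb,
      k = attr(labels, "k"), avg_silhouette = attr(labels, "avg_silhouette"),
      diss = d
    ),
    class = "shape_cluster_model"
  )
}

#' @export
print.shape_cluster_model <- function(x, ...) {
  cat(
    "<shape_cluster_model>", length(x$labels), "strings in", x$k,
    "clusters; avg silhouette",
    if (is.na(x$avg_silhouette)) "NA" else sprintf("%.3f", x$avg_silhouette), "\n"
  )
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Per-string cluster assignment of a fitted shape clustering
#'
#' @param x A `shape_cluster_model`.
#' @param ... Unused.
#' @return Tibble: `string_id`, `cluster`, `is_medoid`, embedding
#'   coordinates `PC1..`.
#' @method tidy shape_cluster_model
#' @export
tidy.shape_cluster_model <- function(x, ...) {
  tibble::tibble(
    string_id = names(x$labels),
    cluster = as.integer(x$labels),
    is_medoid = names(x$labels) %in% x$medoids
  ) |>
    dplyr::bind_cols(tibble::as_tibble(x$embedding))
}

#' One-row summary of a fitted shape clustering
#'
#' @param x A `shape_cluster_model`.
#' @param ... Unused.
#' @return Tibble with `n`, `k`, `avg_silhouette`, `mean_within`,
#'   `mean_between` dissimilarities.
#' @method glance shape_cluster_model
#' @export
glance.shape_cluster_model <- function(x, ...) {
  same <- outer(x$labels, x$labels, "==")
  off <- upper.tri(x$diss)
  tibble::tibble(
    n = length(x$labels),
    k = x$k,
    avg_silhouette = x$avg_silhouette,
    mean_within = mean(x$diss[off & same]),
    mean_between = if (x$k > 1) mean(x$diss[off & !same]) else NA_real_
  )
}

#' MDS plot of a shape clustering
#'
#' Scatter of the first two principal coordinates coloured by cluster,
#' medoids highlighted.
#'
#' @param object A `shape_cluster_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_cluster_model
#' @export
#' @importFrom ggplot2 autoplot
autoplot.shape_cluster_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(
      data = df[df$is_medoid, ],
      shape = 17, size = 3, show.legend = FALSE
    ) +
    ggplot2::labs(colour = "cluster", title = "Pocket shapes (classical MDS)") +
    ggplot2::theme_minimal()
}

#' Hierarchical clustering of bit positions
#'
#' Agglomerative complete-linkage clustering of the bit columns, using
#' `1 - SFT` between the column vectors, giving the column (leaf) order
#' for two-way heat-map export. All-zero columns are mutually identical
#' (distance 0) and flagged with a message.
#'
#' @param bits Logical bit matrix (strings x bits) or `shape_strings`.
#' @return List with `order` (leaf order of columns) and `hclust`.
#' @export
cluster_bits <- function(bits) {
  if (inherits(bits, "shape_strings")) bits <- bits$bits
  if (ncol(bits) < 2) stop("need at least 2 bit columns")
  if (any(colSums(bits) == 0)) {
    message("cluster_bits: ", sum(colSums(bits) == 0), " constant all-zero column(s)")
  }
  d <- dissimilarity_matrix(t(bits))
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  list(order = hc$order, hclust = hc)
}

# Normalised mutual information between two categorical vectors
# (sqrt normalisation); 0 when either variable is constant.
nmi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  p <- tab / n
  e <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / e[nz]))
  mi / sqrt(hx * hy)
}

# Fraction of variance of y explained by the grouping g (one-way
# between-group sum of squares over total).
eta_squared <- function(y, g) {
  g <- factor(g)
  if (nlevels(g) < 2) return(0)
  tot <- sum((y - mean(y))^2)
  if (tot == 0) return(0)
  means <- tapply(y, g, mean)
  between <- sum(tabulate(g) * (means - mean(y))^2)
  between / tot
}

#' Associate pocket-shape variation with residues
#'
#' Operationalises the visual "colour the MDS plot by rotamer status"
#' analysis: each string's rotamer state per residue is taken from its
#' representative (lowest-id) conformer, and for every residue the
#' between-rotamer-state variance fraction (eta squared) along each
#' principal coordinate and the normalised mutual information with the
#' cluster labels are computed. Residues are ranked by their best score.
#'
#' @param strings A `shape_strings` collection.
#' @param conformers Conformer matrix (ids = row numbers).
#' @param embedding MDS embedding from [mds_embed()] or the fitted model.
#' @param labels Cluster labels from [assign_clusters()].
#' @param residues Residue keys to score (default: all conformer columns).
#' @return Tibble: `res_key`, `eta2_PC1..`, `nmi`, `score`, `rank`,
#'   sorted by decreasing score.
#' @export
key_residue_association <- function(strings, conformers, embedding, labels,
                                    residues = colnames(conformers)) {
  rep_conf <- vapply(strings$conformers, min, numeric(1))
  states <- conformers[rep_conf, residues, drop = FALSE]
  axes <- colnames(embedding)
  rows <- purrr::map_dfr(residues, function(r) {
    st <- states[, r]
    e2 <- vapply(axes, function(a) eta_squared(embedding[, a], st), numeric(1))
    out <- tibble::tibble(res_key = r)
    for (a in axes) out[[paste0("eta2_", a)]] <- e2[[a]]
    out$nmi <- nmi(st, labels)
    out$score <- max(c(e2, out$nmi))
    out
  })
  rows |>
    dplyr::arrange(dplyr::desc(.data$score), .data$res_key) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Side-chain rmsd between two conformers
#'
#' Root-mean-square deviation over the side-chain atoms beyond C-beta of
#' the given residues, matched by atom name - the structure-level check
#' that shape clusters are also tight in coordinate space.
#'
#' @param placements A `rotamer_placements`.
#' @param a,b Named assignment rows (conformer matrix rows).
#' @param residues Residue keys to include (default all).
#' @return RMSD in Angstrom.
#' @export
conformer_rmsd <- function(placements, a, b, residues = placements$residues) {
  sq <- c()
  for (k in residues) {
    pa <- placements$placements[[k]][[a[[k]]]]
    pb <- placements$placements[[k]][[b[[k]]]]
    pa <- pa[!(pa$elety %in% c("CB")), ]
    pb <- pb[!(pb$elety %in% c("CB")), ]
    m <- match(pa$elety, pb$elety)
    sq <- c(sq, rowSums((coords(pa) - coords(pb)[m, , drop = FALSE])^2))
  }
  sqrt(mean(sq))
}
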