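test_that("classical MDS reproduces closed forms", {
  # two points at dissimilarity 0.4 -> coordinates +-0.2 on axis 1
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  emb2 <- mds_embed(d2, dims = 1)
  expect_equal(sort(emb2[, 1]), c(-0.2, 0.2), tolerance = 1e-9)

  # three mutually equidistant points -> equilateral triangle
  d3 <- matrix(0.6, 3, 3)
  diag(d3) <- 0
  emb3 <- mds_embed(d3, dims = 2)
  dd <- as.matrix(stats::dist(emb3))
  expect_equal(dd[upper.tri(dd)], rep(0.6, 3), tolerance = 1e-9)

  # a Euclidean-embeddable matrix is reproduced exactly
  set.seed(21)
  x <- matrix(rnorm(12), 6, 2)
  dx <- as.matrix(stats::dist(x))
  embx <- mds_embed(dx, dims = 2)
  expect_equal(as.matrix(stats::dist(embx)), dx, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("MDS is deterministic with the sign convention and pads dims", {
  set.seed(22)
  x <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(stats::dist(x))
  e1 <- mds_embed(d, dims = 3)
  e2 <- mds_embed(d, dims = 3)
  expect_identical(e1, e2)
  for (j in 1:3) {
    v <- e1[, j]
    if (any(v != 0)) expect_gt(v[which.max(abs(v))], 0)
  }
  expect_equal(unname(e1[, 3]), rep(0, 5)) # only 2 informative axes
  expect_warning(z <- mds_embed(matrix(0, 3, 3), dims = 2), "zero")
  expect_equal(unname(z), matrix(0, 3, 2))
})

test_that("k-medoids handles the degenerate cluster counts", {
  set.seed(23)
  x <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(1:8, 1:8)
  one <- assign_clusters(d, k = 1)
  expect_equal(as.integer(one), rep(1L, 8))
  all_own <- assign_clusters(d, k = 8)
  expect_equal(as.integer(all_own), 1:8)
  expect_error(assign_clusters(d, k = 9), "exceeds")
  expect_identical(assign_clusters(d, k = 3), assign_clusters(d, k = 3))
})

test_that("planted separation is recovered, within < between dissimilarity", {
  planted <- make_planted_clusters(
    n_strings = 60, n_bits = 80, k = 3,
    noise_bits = 2, seed = 31
  )
  s <- deduplicate(planted$bits)
  # conserve the mapping back to planted labels via first conformer id
  d <- dissimilarity_matrix(s)
  labels <- assign_clusters(d, k = 3)
  truth <- planted$labels[vapply(s$conformers, min, numeric(1))]
  expect_gte(mclust::adjustedRandIndex(labels, truth), 0.95)
  model <- fit_shape_clusters(d, k = 3)
  g <- glance(model)
  expect_lt(g$mean_within, g$mean_between)
})

test_that("medoids agree with exhaustive search and break ties low", {
  set.seed(24)
  x <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(1:12, 1:12)
  members <- c("2", "5", "9", "11")
  med <- find_medoid(d, members)
  avg <- sapply(members, function(m) mean(d[m, setdiff(members, m)]))
  expect_equal(med, members[which.min(avg)])
  expect_equal(find_medoid(d, "7"), "7")
  # symmetric two-member cluster: lower id wins
  dsym <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("3", "8"), c("3", "8")))
  expect_equal(find_medoid(dsym, c("8", "3")), "3")
})

test_that("fitted cluster models expose tidy, glance and autoplot", {
  pipe <- toy_pipeline()
  model <- pipe$model
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(pipe$merged$bits))
  expect_true(all(c("string_id", "cluster", "is_medoid", "PC1") %in% names(td)))
  expect_equal(sum(td$is_medoid), model$k)
  for (cl in seq_len(model$k)) {
    m <- model$medoids[[as.character(cl)]]
    expect_true(m %in% td$string_id[td$cluster == cl]) # medoid is a member
  }
  g <- glance(model)
  expect_equal(g$n, nrow(td))
  expect_s3_class(ggplot2::autoplot(model), "ggplot")
})

test_that("bit-column clustering merges identical columns first", {
  bits <- cbind(
    a = c(TRUE, TRUE, FALSE, FALSE),
    b = c(TRUE, TRUE, FALSE, FALSE), # identical to a
    c = c(FALSE, FALSE, TRUE, TRUE),
    d = c(TRUE, FALSE, TRUE, FALSE)
  )
  cb <- cluster_bits(bits)
  expect_equal(length(cb$order), 4)
  first_merge <- cb$hclust$merge[1, ]
  expect_setequal(abs(first_merge), c(1, 2))
  expect_equal(cb$hclust$height[1], 0)
  expect_error(cluster_bits(bits[, 1, drop = FALSE]), "at least 2")
})

test_that("complete-linkage merge order matches a hand-traced run", {
  # hand-built distances: d(1,2)=0.1, d(3,4)=0.2, cross in [0.6, 0.8]
  # complete linkage: {1,2} at 0.1, {3,4} at 0.2, all at max cross = 0.8
  d <- matrix(c(
    0, 0.1, 0.6, 0.7,
    0.1, 0, 0.65, 0.8,
    0.6, 0.65, 0, 0.2,
    0.7, 0.8, 0.2, 0
  ), 4, 4, byrow = TRUE)
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  expect_equal(hc$height, c(0.1, 0.2, 0.8), tolerance = 1e-12)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
  expect_setequal(abs(hc$merge[2, ]), c(3, 4))
})

test_that("constructed rotamer dependence yields eta-squared of one", {
  # strings 1..6; residue R1's rotamer index determines PC1 exactly,
  # residue R2 is independent of both axes
  conformers <- cbind("R:1" = c(1L, 1L, 2L, 2L, 3L, 3L), "R:2" = c(1L, 2L, 1L, 2L, 1L, 2L))
  strings <- pocketshapes:::new_shape_strings(
    bits = matrix(runif(6 * 4) < 0.5, 6, 4),
    conformers = as.list(1:6), point_ids = 1:4
  )
  emb <- cbind(
    PC1 = c(-1, -1, 0, 0, 1, 1),
    PC2 = c(0.3, -0.2, 0.1, -0.4, 0.2, 0)
  )
  labels <- setNames(c(1L, 1L, 2L, 2L, 3L, 3L), 1:6)
  rep <- key_residue_association(strings, conformers, emb, labels)
  r1 <- rep[rep$res_key == "R:1", ]
  expect_equal(r1$eta2_PC1, 1, tolerance = 1e-12)
  expect_equal(rep$res_key[1], "R:1") # top ranked
  expect_equal(r1$nmi, 1, tolerance = 1e-12) # states == labels here
  # residue with a single observed state scores zero
  conf2 <- cbind("R:1" = rep(1L, 6), "R:2" = c(1L, 2L, 1L, 2L, 1L, 2L))
  rep2 <- key_residue_association(strings, conf2, emb, labels)
  expect_equal(rep2$score[rep2$res_key == "R:1"], 0)
})

test_that("random rotamer states carry no mutual information with labels", {
  set.seed(41)
  n <- 1000
  states <- sample(1:3, n, replace = TRUE)
  labels <- sample(1:4, n, replace = TRUE)
  expect_lt(pocketshapes:::nmi(states, labels), 0.05)
  expect_equal(pocketshapes:::nmi(states, states), 1, tolerance = 1e-12)
})

test_that("two constructed residues drive orthogonal axes", {
  n <- 12
  conformers <- cbind(
    "R:1" = rep(1:2, each = 6),
    "R:2" = rep(rep(1:2, each = 3), 2)
  )
  strings <- pocketshapes:::new_shape_strings(
    bits = matrix(runif(n * 5) < 0.5, n, 5),
    conformers = as.list(1:n), point_ids = 1:5
  )
  emb <- cbind(
    PC1 = ifelse(conformers[, "R:1"] == 1, -1, 1) + rnorm(n, sd = 1e-6),
    PC2 = ifelse(conformers[, "R:2"] == 1, -1, 1) + rnorm(n, sd = 1e-6)
  )
  labels <- setNames(rep(1:2, each = 6), 1:n)
  rep <- key_residue_association(strings, conformers, emb, labels)
  top_pc1 <- rep$res_key[which.max(rep$eta2_PC1)]
  top_pc2 <- rep$res_key[which.max(rep$eta2_PC2)]
  expect_equal(top_pc1, "R:1")
  expect_equal(top_pc2, "R:2")
  expect_false(top_pc1 == top_pc2)
})

test_that("side-chain rmsd between conformers is zero iff assignments match", {
  pipe <- toy_pipeline()
  a <- pipe$conformers[1, ]
  expect_equal(conformer_rmsd(pipe$placements, a, a), 0)
  # pick a conformer differing in a major chi1 well, not a sub-well variant
  k1 <- pipe$placements$residues[1]
  b <- pipe$conformers[which(pipe$conformers[, k1] == 2)[1], ]
  expect_gt(conformer_rmsd(pipe$placements, a, b), 0.1)
})
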