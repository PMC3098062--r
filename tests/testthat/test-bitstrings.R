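test_that("point-atom contacts follow d < vdw + CPD", {
  carbon <- list(x = 0, y = 0, z = 0, vdw = 1.7)
  p <- contact_params(cpd = 0.5)
  expect_true(point_contact(c(0, 0, 0), carbon, p)) # at the centre
  expect_false(point_contact(c(2.3, 0, 0), carbon, p)) # 2.3 >= 2.2
  expect_true(point_contact(c(2.1, 0, 0), carbon, p)) # 2.1 <  2.2
})

test_that("encoding sets exactly the bits of covered conditional points", {
  lat <- pocketshapes:::new_lattice(c(0, 0, 0), 1, rbind(
    c(0, 0, 0), c(3, 0, 0), c(7, 0, 0), c(20, 0, 0)
  ))
  pts <- structure(
    list(
      lattice = lat, always_free = 4L, always_contact = integer(0),
      conditional = c(1L, 2L, 3L), ccr_keys = NULL
    ),
    class = "pocket_points"
  )
  # one atom at x = 3 covers points 2 (d = 0) and not 1 or 3 (d = 3 and 4)
  sets <- list("A:1" = list(2L, integer(0)))
  expect_equal(encode(c("A:1" = 1L), sets, pts), c(FALSE, TRUE, FALSE))
  # retracted side chain: all-zero string
  expect_equal(encode(c("A:1" = 2L), sets, pts), rep(FALSE, 3))
})

test_that("encoding matches a direct distance check on the toy system", {
  pipe <- toy_pipeline()
  set.seed(3)
  rows <- sample(nrow(pipe$conformers), 5)
  lat_xyz <- as.matrix(pipe$lattice$points[, c("x", "y", "z")])
  cond_idx <- match(pipe$points$conditional, pipe$lattice$points$id)
  csets <- rotamer_contact_sets(pipe$placements, pipe$lattice)
  for (t in rows) {
    atoms <- dplyr::bind_rows(lapply(pipe$placements$residues, function(k) {
      pipe$placements$placements[[k]][[pipe$conformers[t, k]]]
    }))
    direct <- rep(FALSE, length(cond_idx))
    for (i in seq_along(cond_idx)) {
      p <- lat_xyz[cond_idx[i], ]
      d <- sqrt((atoms$x - p[1])^2 + (atoms$y - p[2])^2 + (atoms$z - p[3])^2)
      direct[i] <- any(d < atoms$vdw + 0.5)
    }
    expect_equal(unname(encode(pipe$conformers[t, ], csets, pipe$points)), direct)
  }
})

test_that("deduplication conserves conformers and first-seen order", {
  bits <- rbind(
    c(TRUE, FALSE, TRUE),
    c(FALSE, FALSE, TRUE),
    c(TRUE, FALSE, TRUE),
    c(TRUE, FALSE, TRUE),
    c(FALSE, FALSE, TRUE)
  )
  s <- deduplicate(bits)
  expect_equal(nrow(s$bits), 2)
  expect_equal(s$conformers, list(c(1, 3, 4), c(2, 5)), ignore_attr = TRUE)
  expect_equal(sum(lengths(s$conformers)), nrow(bits))
  # all identical
  one <- deduplicate(matrix(TRUE, 5, 3))
  expect_equal(nrow(one$bits), 1)
  expect_equal(one$conformers[[1]], 1:5)
  expect_error(deduplicate(bits, conformer_ids = 1:2), "one conformer id")
})

test_that("deduplication on the pipeline conserves the conformer count", {
  pipe <- toy_pipeline()
  expect_equal(
    sum(lengths(pipe$strings$conformers)),
    nrow(pipe$conformers)
  )
  ids <- sort(unlist(pipe$strings$conformers))
  expect_equal(ids, seq_len(nrow(pipe$conformers)))
  # pruning really collapses near-duplicate rotamer footprints here
  expect_lt(nrow(pipe$strings$bits), nrow(pipe$conformers))
})

test_that("tanimoto matches its defining formula and handles empty shapes", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(TRUE, TRUE), c(TRUE, TRUE)), 1)
  expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_warning(both0 <- tanimoto(c(FALSE, FALSE), c(FALSE, FALSE)), "all-zero")
  expect_equal(both0, 1)
  expect_error(tanimoto(c(TRUE), c(TRUE, FALSE)), "length")

  set.seed(11)
  for (i in 1:200) {
    a <- runif(40) < 0.4
    b <- runif(40) < 0.4
    if (!any(a) && !any(b)) next
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b))
  }
})

test_that("1 - tanimoto behaves as a metric on sampled triples", {
  set.seed(12)
  viol <- 0
  for (i in 1:1000) {
    m <- matrix(runif(3 * 30) < 0.5, 3, 30)
    if (any(rowSums(m) == 0)) next
    d12 <- 1 - tanimoto(m[1, ], m[2, ])
    d13 <- 1 - tanimoto(m[1, ], m[3, ])
    d23 <- 1 - tanimoto(m[2, ], m[3, ])
    if (d12 > d13 + d23 + 1e-12) viol <- viol + 1
  }
  expect_equal(viol, 0)
})

test_that("the dissimilarity matrix equals scalar recomputation", {
  set.seed(13)
  bits <- matrix(runif(10 * 25) < 0.5, 10, 25)
  bits[rowSums(bits) == 0, 1] <- TRUE
  s <- deduplicate(bits)
  d <- dissimilarity_matrix(s)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  for (i in 1:nrow(s$bits)) {
    for (j in 1:nrow(s$bits)) {
      expect_equal(d[i, j], 1 - oracle_tanimoto(s$bits[i, ], s$bits[j, ]))
    }
  }
})

test_that("greedy merging matches the quadratic-scan reference", {
  set.seed(14)
  n <- 60
  bits <- matrix(runif(n * 40) < 0.3, n, 40)
  s <- deduplicate(bits)
  for (thr in c(0, 3, 5, 10)) {
    got <- merge_similar(s, thr)
    ref <- oracle_merge(s$bits, lengths(s$conformers), thr)
    expect_equal(nrow(got$bits), length(ref$reps))
    expect_equal(got$bits, s$bits[ref$reps, , drop = FALSE])
    ref_groups <- lapply(
      split(seq_len(nrow(s$bits)), ref$member),
      function(m) sort(unlist(s$conformers[m]))
    )
    expect_equal(unname(got$conformers), unname(ref_groups[order(as.integer(names(ref_groups)))]),
      ignore_attr = TRUE
    )
  }
})

test_that("merge respects its thresholds and conserves conformers", {
  bits <- rbind(
    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE), # Hamming 2 from row 1
    c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE) # Hamming 7 / 7
  )
  s <- deduplicate(bits)
  merged0 <- merge_similar(s, 0)
  expect_equal(nrow(merged0$bits), 3)
  expect_equal(sort(unlist(merged0$conformers)), sort(unlist(s$conformers)))
  merged <- merge_similar(s, 5)
  expect_equal(nrow(merged$bits), 2)
  expect_equal(sum(lengths(merged$conformers)), 3)
  expect_error(merge_similar(s, -1), ">= 0")
  # monotonicity: larger threshold, no more groups
  set.seed(15)
  rb <- deduplicate(matrix(runif(30 * 20) < 0.5, 30, 20))
  sizes <- vapply(c(0, 2, 4, 8), function(t) nrow(merge_similar(rb, t)$bits), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # single-linkage agrees on group membership closure
  sl <- merge_similar(s, 5, method = "single_linkage")
  expect_equal(nrow(sl$bits), 2)
})

test_that("string tables serialise popcounts and hex patterns", {
  pipe <- toy_pipeline()
  tbl <- tibble::as_tibble(pipe$strings)
  expect_equal(tbl$popcount, unname(rowSums(pipe$strings$bits)))
  expect_equal(sum(tbl$n_conformers), nrow(pipe$conformers))
  expect_equal(nchar(tbl$bits_hex[1]), ceiling(ncol(pipe$strings$bits) / 4))
})
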