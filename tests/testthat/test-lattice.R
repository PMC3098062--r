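# small open-top box scaffold: five walls of carbon pseudo-atoms around a
# cavity, cheap enough for the literal triple-loop oracle
box_scaffold <- function(half = 3.5, spacing = 1.75) {
  g <- seq(-half, half, by = spacing)
  pts <- list()
  for (a in g) {
    for (b in g) {
      pts[[length(pts) + 1]] <- c(a, b, -half) # floor
      pts[[length(pts) + 1]] <- c(-half, a, b) # four walls
      pts[[length(pts) + 1]] <- c(half, a, b)
      pts[[length(pts) + 1]] <- c(a, -half, b)
      pts[[length(pts) + 1]] <- c(a, half, b)
    }
  }
  xyz <- unique(do.call(rbind, pts))
  res <- lapply(seq_len(nrow(xyz)), function(i) {
    list(
      chain = "B", resno = i, resid = "ALA",
      atoms = setNames(list(xyz[i, ]), "CA")
    )
  })
  mini_structure(res, source = "box")
}

test_that("lattice generation matches the literal brute-force scan", {
  st <- box_scaffold()
  ens <- carbon_ensemble(c(0, 0, -1))
  keys <- residue_table(st)$res_key
  lat <- generate_pocket_points(st, ens, keys,
    spacing = 1, trim_cutoff = 5,
    cavity_min_dirs = 4, cavity_range = 6
  )
  oracle <- oracle_lattice(st, ens, keys,
    spacing = 1, trim_cutoff = 5,
    cavity_min_dirs = 4, cavity_range = 6
  )
  got <- as.matrix(lat$points[, c("i", "j", "k")])
  expect_equal(
    sort(apply(got, 1, paste, collapse = ",")),
    sort(apply(oracle, 1, paste, collapse = ","))
  )
  # points inside a vdW sphere or beyond the trim distance are absent
  d_atom <- pocketshapes:::min_dist(
    as.matrix(lat$points[, c("x", "y", "z")]),
    as.matrix(st$atoms[, c("x", "y", "z")])
  )
  expect_true(all(d_atom >= min(st$atoms$vdw)))
  d_anchor <- pocketshapes:::min_dist(
    as.matrix(lat$points[, c("x", "y", "z")]),
    rbind(as.matrix(st$atoms[, c("x", "y", "z")]), as.matrix(ens[, c("x", "y", "z")]))
  )
  expect_true(all(d_anchor < 5))
})

test_that("shrinking the trim cutoff never adds points and ids are stable", {
  st <- box_scaffold()
  ens <- carbon_ensemble(c(0, 0, -1))
  keys <- residue_table(st)$res_key
  lat6 <- generate_pocket_points(st, ens, keys, trim_cutoff = 5, cavity_range = 6)
  lat4 <- generate_pocket_points(st, ens, keys, trim_cutoff = 4, cavity_range = 6)
  key6 <- apply(lat6$points[, c("i", "j", "k")], 1, paste, collapse = ",")
  key4 <- apply(lat4$points[, c("i", "j", "k")], 1, paste, collapse = ",")
  expect_true(all(key4 %in% key6))
  # lexicographic id order
  p <- lat6$points
  expect_true(!is.unsorted(order(p$i, p$j, p$k)))
  expect_equal(p$id, seq_len(nrow(p)))
  # rerun is identical
  lat6b <- generate_pocket_points(st, ens, keys, trim_cutoff = 5, cavity_range = 6)
  expect_identical(lat6$points, lat6b$points)
})

test_that("point classification partitions exactly and ignores conformer order", {
  lat <- pocketshapes:::new_lattice(c(0, 0, 0), 1, rbind(
    c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)
  ))
  # ids 1..4 = a, b, c, d; sets {a,b} and {b,c}
  sets <- list(c(1L, 2L), c(2L, 3L))
  pts <- classify_points(lat, sets)
  expect_equal(pts$always_contact, 2L)
  expect_equal(pts$always_free, 4L)
  expect_equal(pts$conditional, c(1L, 3L))
  rev_pts <- classify_points(lat, rev(sets))
  expect_equal(rev_pts[c("always_free", "always_contact", "conditional")],
    pts[c("always_free", "always_contact", "conditional")])
  # single conformer: nothing is conditional
  expect_message(
    single <- classify_points(lat, list(c(1L, 2L))),
    "no conditional"
  )
  expect_equal(length(single$conditional), 0)
  expect_equal(single$always_contact, c(1L, 2L))
  # partition is exact on the real system too
  pipe <- toy_pipeline()
  pp <- pipe$points
  expect_equal(
    sort(c(pp$always_free, pp$always_contact, pp$conditional)),
    pp$lattice$points$id
  )
})

test_that("second-layer selection honours the 3 A boundary from contact points", {
  lat <- pocketshapes:::new_lattice(c(0, 0, 0), 1, rbind(c(1, 0, 0), c(30, 0, 0)))
  mk <- function(d) {
    mini_structure(list(
      list(chain = "A", resno = 1, resid = "ALA", atoms = list(CB = c(0, 0, 0))),
      list(chain = "A", resno = 2, resid = "LEU", atoms = list(CB = c(1 + d, 0, 0)))
    ))
  }
  near <- select_slr(mk(2.9), lat, "A:1", cutoff = 3)
  expect_equal(near$res_key, "A:2")
  expect_error(select_slr(mk(3.2), lat, "A:1", cutoff = 3), "no second-layer")
})

test_that("conditional-contact residues require a conditional touch", {
  slr <- c("A:1", "A:2", "A:3")
  touches <- list("A:1" = integer(0), "A:2" = 5L, "A:3" = c(2L, 9L))
  expect_equal(identify_ccrs(slr, touches), c("A:2", "A:3"))
})

test_that("points export carries the class labels", {
  pipe <- toy_pipeline()
  tbl <- points_table(pipe$points)
  expect_equal(nrow(tbl), nrow(pipe$points$lattice$points))
  expect_equal(sum(tbl$class == "conditional"), length(pipe$points$conditional))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_points_pdb(pipe$points, path)
  expect_true(file.exists(path))
})
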