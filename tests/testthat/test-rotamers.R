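test_that("rotamer library TSV round trips and validates chi counts", {
  lib <- dplyr::bind_rows(
    canonical_rotamers("LEU", 3),
    canonical_rotamers("SER", 2),
    canonical_rotamers("LYS", 4)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rotamer_library(lib, path)
  back <- load_rotamer_library(path)
  expect_equal(nrow(back), nrow(lib))
  expect_equal(back$chi1, lib$chi1)
  expect_true(all(is.na(back$chi2[back$res_name == "SER"])))

  bad <- lib
  bad$chi2[bad$res_name == "SER"][1] <- 60 # SER has one chi
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_rotamer_library(bad, path2)
  expect_error(load_rotamer_library(path2), "exactly 1 chi")
  bad2 <- lib
  bad2$chi2[bad2$res_name == "LEU"][1] <- NA
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_rotamer_library(bad2, path3)
  expect_error(load_rotamer_library(path3), "exactly 2 chi")
})

test_that("angles normalise to (-180, 180]", {
  lib <- canonical_rotamers("SER", 1)
  lib$chi1 <- 270
  expect_equal(pocketshapes:::validate_rotamer_library(lib)$chi1, -90)
})

test_that("side-chain building reproduces the requested chi angles", {
  res <- ideal_residue("LYS")
  st <- mini_structure(list(res))
  ratoms <- st$atoms
  for (chi in list(c(-60, 180, 65, -170), c(62, -57, 180, 60))) {
    sc <- apply_rotamer(ratoms, "LYS", chi)
    full <- dplyr::bind_rows(ratoms, sc)
    expect_equal(measure_chi(full, "LYS"), chi, tolerance = 1e-3)
  }
  # aromatic ring: chi round trip plus ring bond lengths from the table
  sc <- apply_rotamer(ratoms |> dplyr::mutate(resid = "TYR"), "TYR", c(-65, 95))
  full <- dplyr::bind_rows(ratoms, sc)
  expect_equal(measure_chi(full, "TYR"), c(-65, 95), tolerance = 1e-3)
  at <- function(e) as.numeric(sc[sc$elety == e, c("x", "y", "z")])
  expect_equal(sqrt(sum((at("CZ") - at("CE1"))^2)), 1.39, tolerance = 1e-9)
})

test_that("rotating chi1 by 180 degrees moves only atoms beyond C-beta", {
  st <- mini_structure(list(ideal_residue("LEU")))
  a <- apply_rotamer(st$atoms, "LEU", c(-60, 180))
  b <- apply_rotamer(st$atoms, "LEU", c(120, 180))
  expect_equal(a[a$elety == "CB", c("x", "y", "z")],
    b[b$elety == "CB", c("x", "y", "z")],
    ignore_attr = TRUE
  )
  moved <- c("CG", "CD1", "CD2")
  for (e in moved) {
    expect_gt(sum(abs(a[a$elety == e, c("x", "y", "z")] - b[b$elety == e, c("x", "y", "z")])), 0.5)
  }
  # determinism: identical chi, identical coordinates
  expect_identical(
    apply_rotamer(st$atoms, "LEU", c(-60, 180)),
    apply_rotamer(st$atoms, "LEU", c(-60, 180))
  )
})

test_that("round trip on a built side chain recovers atom positions", {
  st <- mini_structure(list(ideal_residue("LEU")))
  sc <- apply_rotamer(st$atoms, "LEU", c(-72, 161))
  full <- dplyr::bind_rows(st$atoms, sc)
  chi <- measure_chi(full, "LEU")
  rebuilt <- apply_rotamer(full[full$is_backbone | full$elety == "CB", ], "LEU", chi)
  expect_equal(as.matrix(rebuilt[, c("x", "y", "z")]),
    as.matrix(sc[match(rebuilt$elety, sc$elety), c("x", "y", "z")]),
    tolerance = 0.3, ignore_attr = TRUE
  )
})

test_that("the soft clash criterion follows d < r1 + r2 - CTD", {
  carbon <- function(x) list(x = x, y = 0, z = 0, vdw = 1.7)
  p <- clash_params(ctd = 1.0)
  expect_false(clash(carbon(0), carbon(3.4), p)) # 3.4 >= 2.4
  expect_true(clash(carbon(0), carbon(2.3), p)) # 2.3 <  2.4
  expect_true(clash(carbon(0), carbon(0), p)) # coincident
  # symmetry
  expect_equal(clash(carbon(0), carbon(2.3), p), clash(carbon(2.3), carbon(0), p))
  # CTD = 0 is the strict vdW test
  expect_true(clash(carbon(0), carbon(3.3), clash_params(ctd = 0)))
  expect_false(clash(carbon(0), carbon(3.5), clash_params(ctd = 0)))
})

test_that("prefiltered survivors equal a direct all-pairs scan", {
  sys <- toy_system()
  st <- sys$template
  keys <- sys$flexible_keys
  pl <- prefilter_rotamers(st, sys$library, keys)
  fixed <- st$atoms[st$atoms$is_backbone | !(st$atoms$res_key %in% keys), ]
  fx <- fixed$x
  fy <- fixed$y
  fz <- fixed$z
  bbd <- c(N = 1, CA = 0, C = 1, O = 2, OXT = 2)[fixed$elety]
  for (k in keys) {
    ratoms <- st$atoms[st$atoms$res_key == k, ]
    lib <- sys$library[sys$library$res_name == ratoms$resid[1], ]
    depths <- pocketshapes:::sidechain_depths(ratoms$resid[1])
    same <- fixed$res_key == k
    prev_c <- fixed$chain == ratoms$chain[1] &
      fixed$resno == ratoms$resno[1] - 1 & fixed$elety == "C"
    next_n <- fixed$chain == ratoms$chain[1] &
      fixed$resno == ratoms$resno[1] + 1 & fixed$elety == "N"
    survive <- c()
    for (r in seq_len(nrow(lib))) {
      sc <- apply_rotamer(ratoms, ratoms$resid[1], pocketshapes:::chi_of(lib[r, ]))
      ok <- TRUE
      for (i in seq_len(nrow(sc))) {
        d <- sqrt((fx - sc$x[i])^2 + (fy - sc$y[i])^2 + (fz - sc$z[i])^2)
        depth <- depths[[sc$elety[i]]]
        # bonded exemption: own backbone within 3 bonds, CB vs peptide neighbours
        exempt <- (same & !is.na(bbd) & (depth + bbd) <= 3) |
          (depth == 1 & (prev_c | next_n))
        if (any(!exempt & d < sc$vdw[i] + fixed$vdw - 1.0)) {
          ok <- FALSE
          break
        }
      }
      if (ok) survive <- c(survive, lib$rotamer_id[r])
    }
    expect_equal(pl$rotamer_ids[[k]], survive)
  }
})

test_that("raising the clash tolerance never shrinks survivor sets", {
  sys <- toy_system()
  keys <- sys$flexible_keys[1:2]
  prev <- NULL
  for (ctd in c(1.5, 1.0, 0.5)) {
    pl <- prefilter_rotamers(sys$template, sys$library, keys, params = clash_params(ctd = ctd))
    if (!is.null(prev)) {
      for (k in keys) expect_true(all(pl$rotamer_ids[[k]] %in% prev[[k]]))
    }
    prev <- pl$rotamer_ids
  }
})

test_that("flexible residues without backbone or rotamers fail loudly", {
  st <- mini_structure(list(list(
    chain = "A", resno = 1, resid = "LEU",
    atoms = list(CA = c(0, 0, 0)) # CA-only
  )))
  expect_error(
    prefilter_rotamers(st, canonical_rotamers("LEU", 2), "A:1"),
    "lacks backbone"
  )
  st2 <- mini_structure(list(ideal_residue("LEU")))
  expect_error(
    prefilter_rotamers(st2, canonical_rotamers("SER", 2), "A:1"),
    "no entries for LEU"
  )
})
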