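test_that("residue classification is total, deterministic and matches the pH 7.4 scheme", {
  aa20 <- c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
  )
  cls <- classify_residue(aa20)
  expect_length(cls, 20)
  expect_true(all(cls %in% c("positive", "negative", "polar", "apolar")))
  expect_identical(cls, classify_residue(aa20))

  expect_identical(
    classify_residue(c("ARG", "ASP", "SER", "GLY")),
    c("positive", "negative", "polar", "apolar")
  )
  expect_identical(residue_charge(c("ARG", "ASP", "SER", "GLY")), c(1, -1, 0, 0))
  # polar set is exactly ASN, GLN, SER, THR, TYR
  expect_identical(aa20[cls == "polar"], c("ASN", "GLN", "SER", "THR", "TYR"))
  # charged sets
  expect_identical(aa20[cls == "positive"], c("ARG", "LYS"))
  expect_identical(aa20[cls == "negative"], c("ASP", "GLU"))
  # histidine neutral/apolar at this pH
  expect_identical(classify_residue("HIS"), "apolar")
  expect_error(classify_residue("XYZ"), "XYZ")
  # class <-> charge coupling on a model
  m <- make_toy_monomer(ecl_charges = data.frame(
    segment = "ECS1", offset = 2, charge = 1
  ), seed = 3)
  expect_true(all((m$charge_class == "positive") == (m$charge == 1)))
  expect_true(all((m$charge_class == "negative") == (m$charge == -1)))
})

test_that("PDB round trip preserves bead positions, names and charges", {
  m <- make_toy_monomer(seed = 11, ecl_charges = data.frame(
    segment = c("ECS1", "ECS2"), offset = c(1, 2), charge = c(-1, 1)
  ))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, pdb)
  m2 <- load_structure(pdb)
  expect_equal(nrow(m2), nrow(m))
  expect_identical(m2$residue_name, m$residue_name)
  expect_identical(m2$charge, m$charge)
  expect_lt(max(abs(cbind(m2$x, m2$y, m2$z) - cbind(m$x, m$y, m$z))), 1e-3)
  # load -> write -> load is idempotent
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, pdb2)
  m3 <- load_structure(pdb2)
  expect_identical(m3$x, m2$x)
  expect_identical(m3$residue_name, m2$residue_name)
  expect_identical(m3$charge, m2$charge)
})

test_that("bead placement uses the side-chain centroid, falling back to CA", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ARG A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ARG A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ARG A   1       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CG  ARG A   1       2.000   2.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  GLY A   2       5.000   5.000   5.000  1.00  0.00           C",
    "END"
  ), pdb)
  m <- load_structure(pdb)
  expect_equal(nrow(m), 2)
  # ARG bead at centroid of CB, CG (backbone N/CA excluded)
  expect_equal(unlist(m[1, c("x", "y", "z")], use.names = FALSE), c(2, 1, 0))
  # GLY has no side-chain heavy atoms -> CA
  expect_equal(unlist(m[2, c("x", "y", "z")], use.names = FALSE), c(5, 5, 5))
  expect_identical(m$charge, c(1, 0))
  # chain selection and errors
  expect_error(load_structure(pdb, chain = "Z"), "chain")
  expect_error(load_structure(tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  XXX A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), bad)
  expect_error(load_structure(bad), "XXX")
})

test_that("C-terminal truncation drops the tail and conserves remaining charge", {
  # a long cytoplasmic tail beyond the boundary is removed entirely
  tail_len <- 111
  core <- make_toy_monomer(seed = 5)
  n_core <- nrow(core)
  tail <- tibble::tibble(
    residue_index = n_core + seq_len(tail_len), residue_name = "GLU",
    chain_id = "A", x = 0, y = 0, z = -seq_len(tail_len), radius = 2.64,
    segment = "cterm"
  )
  full <- bead_model(dplyr::bind_rows(tibble::as_tibble(core), tail), "tailed")
  trunc <- truncate_cterm(full, n_core)
  expect_equal(nrow(trunc), n_core)
  expect_equal(net_charge(trunc), net_charge(full) - sum(tail$residue_name == "GLU") * -1)
  # boundary at the last residue is a no-op
  expect_equal(nrow(truncate_cterm(full, max(full$residue_index))), nrow(full))
  expect_error(truncate_cterm(full, 0), "outside")
  expect_error(truncate_cterm(full, nrow(full) + 1), "outside")
})

test_that("cterm-flagged beads are excluded from energetics, not silently included", {
  m <- make_toy_monomer(seed = 5)
  tail <- tibble::tibble(
    residue_index = nrow(m) + 1:3, residue_name = "LYS", chain_id = "A",
    x = c(30, 31, 32), y = 0, z = 0, radius = 2.64, segment = "cterm"
  )
  tailed <- bead_model(dplyr::bind_rows(tibble::as_tibble(m), tail), "tailed")
  probe <- bead_model(tibble::tibble(
    residue_index = 1, residue_name = "ASP", chain_id = "B",
    x = 35, y = 0, z = 0, radius = 2.64
  ), "probe")
  e_tailed <- interaction_energy(tailed, probe)
  e_clean <- interaction_energy(m, probe)
  expect_equal(e_tailed$e_total, e_clean$e_total, tolerance = 1e-12)
})

test_that("membrane-frame alignment is rigid and recovers a rotated bundle", {
  m <- make_toy_monomer(seed = 21)
  rotated <- random_rigid(m, seed = 99)
  aligned <- align_to_membrane_frame(rotated)
  # rigid: pairwise distances preserved to 1e-6
  expect_lt(max(abs(pairwise_dists(aligned) - pairwise_dists(m))), 1e-6)
  expect_equal(net_charge(aligned), net_charge(m))
  # recovered orientation superposes on the original frame
  orig_aligned <- align_to_membrane_frame(m)
  expect_lt(
    superpose_rmsd(
      cbind(orig_aligned$x, orig_aligned$y, orig_aligned$z),
      cbind(aligned$x, aligned$y, aligned$z)
    ),
    1e-3
  )
  # principal axis of the result is +z and ECS points up
  tm <- aligned[grepl("^TM", aligned$segment), ]
  ev <- eigen(stats::cov(cbind(tm$x, tm$y, tm$z)))$vectors[, 1]
  expect_gt(abs(ev[3]), 1 - 1e-6)
  expect_gt(mean(aligned$z[grepl("^ECS", aligned$segment)]), 0)
  # TM centroid at the origin
  expect_lt(max(abs(colMeans(cbind(tm$x, tm$y, tm$z)))), 1e-8)
  # degenerate input refused
  line <- bead_model(tibble::tibble(
    residue_index = 1:5, residue_name = "GLY", chain_id = "A",
    x = 1:5, y = 0, z = 0, radius = 1
  ), "line")
  expect_error(align_to_membrane_frame(line), "collinear")
})

test_that("bead CSV round trip preserves the full table", {
  m <- make_toy_monomer(seed = 2, ecl_charges = data.frame(
    segment = "ECS1", offset = 4, charge = -1
  ))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_bead_csv(m, csv)
  m2 <- read_bead_csv(csv)
  expect_equal(m2$x, m$x)
  expect_identical(m2$residue_name, m$residue_name)
  expect_identical(m2$segment, m$segment)
  expect_equal(net_charge(m2), net_charge(m))
})
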