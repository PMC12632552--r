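test_that("atom-37 template is a fixed per-type bijection with the known extremes", {
  for (rt in AA3) {
    atoms <- residue_atom_names(rt)
    idx <- slot_index(rt, atoms)
    expect_false(anyNA(idx))
    expect_equal(length(unique(idx)), length(atoms))  # injective
    expect_true(all(idx >= 1 & idx <= 37))
  }
  counts <- vapply(AA3, function(rt) length(residue_atom_names(rt)),
                   integer(1))
  expect_equal(unname(counts[["GLY"]]), 4L)
  expect_equal(names(which.max(counts)), "TRP")
  expect_equal(ATOM37_NAMES[1:5], c("N", "CA", "C", "CB", "O"))
})

test_that("PDB write/read round-trips fixture structures within format precision", {
  for (preset in c("helix", "coil")) {
    s <- test_peptide("ACDEFGHIKLMNPQRSTVWY", preset, seed = 7L)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(s, f)
    s2 <- read_pdb(f)
    expect_identical(s2$residue_types, s$residue_types)
    expect_identical(s2$atom_mask, s$atom_mask)
    expect_lt(max(abs(s2$coords - s$coords)), 1e-3)
    # ATOM record count equals occupied mask entries
    expect_equal(sum(grepl("^ATOM", readLines(f))), sum(s$atom_mask))
  }
})

test_that("reader keeps the higher-occupancy altloc, drops hydrogens, skips non-canonicals", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   9.000   9.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.422   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       3.247   1.400   0.000  1.00  0.00           O",
    "ATOM      6  CB  ALA A   1       2.000  -1.000   1.000  1.00  0.00           C",
    "ATOM      7  HB1 ALA A   1       2.500  -1.500   1.500  1.00  0.00           H",
    "HETATM    8  C1  XYZ A   2       5.000   5.000   5.000  1.00  0.00           C",
    "END"), f)
  s <- suppressWarnings(read_pdb(f))
  expect_equal(s$n_residues, 1L)
  # single-alanine: exactly the 5 heavy-atom slots
  expect_equal(sum(s$atom_mask), 5L)
  expect_equal(which(s$atom_mask[1, ]),
               unname(sort(slot_index("ALA", c("N", "CA", "C", "O", "CB")))))
  # higher-occupancy altloc B kept
  expect_equal(s$coords[1, slot_index("ALA", "N"), ], c(9, 9, 9))
})

test_that("reader errors on files without canonical protein residues", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(suppressWarnings(read_pdb(f)))
  expect_error(read_pdb(file.path(tempdir(), "does_not_exist_xyz.pdb")))
})

test_that("default chain label A is written for empty chain labels", {
  s <- test_peptide("AG", "strand")
  s$chain_labels <- c("", "")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  chains <- unique(substr(grep("^ATOM", readLines(f), value = TRUE), 22, 22))
  expect_equal(chains, "A")
})

test_that("all-atom RMSD is zero under identity and rigid motion, and matches the hand formula unaligned", {
  s <- test_peptide()
  expect_equal(all_atom_rmsd(s, s), 0)
  shifted <- transform_structure(s, diag(3), c(5, 0, 0))
  expect_lt(all_atom_rmsd(s, shifted), 1e-8)
  rt <- random_rigid_motion(11)
  moved <- transform_structure(s, rt$rotation, rt$translation)
  expect_lt(all_atom_rmsd(s, moved), 1e-8)
  expect_equal(all_atom_rmsd(s, moved), all_atom_rmsd(moved, s),
               tolerance = 1e-12)

  # 4-atom toy: one atom displaced by d, superposition disabled -> d/sqrt(N)
  coords <- array(0, dim = c(1, 37, 3))
  mask <- matrix(FALSE, 1, 37)
  pts <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0), c(3, 1.4, 0.5))
  slots <- slot_index("ALA", c("N", "CA", "C", "O"))
  for (k in 1:4) { coords[1, slots[k], ] <- pts[k, ]; mask[1, slots[k]] <- TRUE }
  a <- all_atom_structure("ALA", coords, mask)
  d <- 0.8
  coords2 <- coords
  coords2[1, slots[4], ] <- pts[4, ] + c(0, 0, d)
  b <- all_atom_structure("ALA", coords2, mask)
  expect_equal(all_atom_rmsd(a, b, superpose = FALSE), d / sqrt(4),
               tolerance = 1e-12)
})

test_that("RMSD rejects incompatible structures", {
  a <- test_peptide("ACD")
  b <- test_peptide("ACE")
  expect_error(all_atom_rmsd(a, b), "incompatible")
})
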