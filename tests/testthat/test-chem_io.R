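# Reading, standardization, filtering, enantiomer augmentation, prediction
# output.

test_that("SMILES files are read in order, invalid entries skipped and counted", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene"), f)
  recs <- read_molecules(f, "smiles")
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$id, "benzene")
  expect_identical(sum(recs[[1]]$atoms$element != "H"), 6L)
  expect_identical(mol_net_charge(recs[[1]]), 0L)
  expect_identical(attr(recs, "n_skipped"), 0L)

  writeLines(character(0), f)
  expect_length(read_molecules(f, "smiles"), 0L)
  expect_identical(attr(read_molecules(f, "smiles"), "n_skipped"), 0L)

  writeLines(c("CCO", "C1CC"), f)
  recs <- quiet_ob(read_molecules(f, "smiles"))
  expect_length(recs, 1L)
  expect_identical(attr(recs, "n_skipped"), 1L)

  expect_error(read_molecules(file.path(tempdir(), "nope.smi")), "cannot read")
})

test_that("SDF round trip preserves molecules and predictions", {
  f <- withr::local_tempfile(fileext = ".sdf")
  preds <- data.frame(id = c("a", "a"), smiles = c("CC(=O)O", "CC(=O)O"),
                      atom_index = c(3L, 1L), reaction = c("acidic", "basic"),
                      pka = c(4.5612, 9.1), stringsAsFactors = FALSE)
  write_predictions(preds, f, "sdf")
  back <- read_molecules(f, "sdf")
  expect_length(back, 2L)
  expect_identical(back[[1]]$smiles, ob_canonical("CC(=O)O"))
})

test_that("standardize neutralizes, keeps the largest fragment, and is idempotent", {
  m <- standardize(mol_from_smiles("CC(=O)[O-]", "acetate"))
  expect_identical(m$smiles, ob_canonical("CC(=O)O"))
  expect_identical(mol_net_charge(m), 0L)

  m2 <- standardize(mol_from_smiles("CC(=O)O.[Na+]", "salt"))
  expect_identical(m2$smiles, ob_canonical("CC(=O)O"))
  expect_false("Na" %in% m2$atoms$element)

  bz <- fix_mols()$benzene
  expect_identical(bz$smiles, ob_canonical("c1ccccc1"))
  expect_identical(standardize(bz)$smiles, bz$smiles)

  # explicit hydrogens and conformer
  expect_identical(sum(bz$atoms$nH), 0L)
  expect_identical(nrow(bz$coords), n_atoms(bz))
  # canonical SMILES round-trips idempotently
  expect_identical(ob_canonical(bz$smiles), bz$smiles)
})

test_that("a fragment with no neutralization rule is flagged, not dropped", {
  expect_message(
    m <- standardize(mol_from_smiles("C[N+](C)(C)C", "tma")),
    "no neutralization rule")
  expect_true(m$flagged)
  expect_identical(mol_net_charge(m), 1L)
})

test_that("element filter keeps drug-like organics only", {
  expect_true(element_filter(fix_mols()$benzene))
  ferrocene <- quiet_ob(mol_from_smiles("[Fe+2].c1cc[cH-]c1.c1cc[cH-]c1"))
  expect_false(element_filter(ferrocene))
  sih4 <- quiet_ob(mol_from_smiles("[SiH4]"))
  expect_false(element_filter(sih4))
})

test_that("pKa range filter is inclusive [0, 14] and rejects NaN", {
  expect_true(pka_range_filter(7.4))
  expect_false(pka_range_filter(-0.5))
  expect_true(pka_range_filter(14.0))
  expect_true(pka_range_filter(0))
  expect_false(pka_range_filter(14.0001))
  expect_error(pka_range_filter(NaN), "NaN")
})

test_that("stereocenter inversion is the enantiomer and an involution", {
  ala <- fix_mols()$alanine
  inv <- invert_stereocenters(ala)
  expect_identical(inv$smiles, ob_canonical("N[C@H](C)C(=O)O"))
  # mirrored conformer, not re-embedded
  expect_equal(inv$coords[, 1], -ala$coords[, 1])
  expect_equal(inv$coords[, 2:3], ala$coords[, 2:3])
  # involution
  back <- invert_stereocenters(inv)
  expect_identical(back$smiles, ala$smiles)
  # achiral molecules yield no augmentation
  expect_null(invert_stereocenters(fix_mols()$benzene))
})

test_that("prediction CSV has the contract columns and round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  preds <- data.frame(id = "x", smiles = "CC(=O)O", atom_index = 3L,
                      reaction = "acidic", pka = 4.5612,
                      stringsAsFactors = FALSE)
  write_predictions(preds, f, "csv")
  back <- read_predictions(f)
  expect_identical(names(back),
                   c("id", "smiles", "atom_index", "reaction", "pka"))
  expect_equal(round(back$pka, 4), round(preds$pka, 4))
  expect_identical(back$atom_index, preds$atom_index)

  write_predictions(preds[0, ], f, "csv")
  empty <- read_predictions(f)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty),
                   c("id", "smiles", "atom_index", "reaction", "pka"))
})
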