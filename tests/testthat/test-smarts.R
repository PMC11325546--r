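# Subset-SMARTS matcher and exact heavy-atom isomorphism.

test_that("atom primitives match elements, aromaticity, H counts, charge and rings", {
  phe <- fix_mols()$phenol
  expect_identical(match_sites(compile_smarts("[OX2H1]c"), phe), 1L)
  expect_identical(match_sites(compile_smarts("[OX2H1]"), phe), 1L)
  expect_length(match_sites(compile_smarts("[NX3]"), phe), 0L)
  # aromatic vs aliphatic element forms
  expect_length(match_sites(compile_smarts("C"), fix_mols()$benzene), 0L)
  expect_length(match_sites(compile_smarts("c"), fix_mols()$benzene), 6L)
  # ring primitives
  expect_length(match_sites(compile_smarts("[R]"), fix_mols()$benzene), 6L)
  expect_length(match_sites(compile_smarts("[R0]"), fix_mols()$benzene), 0L)
  expect_length(match_sites(compile_smarts("[r6]"), fix_mols()$pyridine), 6L)
  # charge
  oac <- mol_from_smiles("CC(=O)[O-]")
  expect_length(match_sites(compile_smarts("[O-]"), oac), 1L)
  # negation and or
  expect_identical(sort(match_sites(compile_smarts("[!C;!H3]"),
                                    mol_from_smiles("CCO"))), 3L)
  expect_length(match_sites(compile_smarts("[O,N]"),
                            mol_from_smiles("NCCO")), 2L)
})

test_that("bond primitives and topology constrain matches", {
  acetic <- fix_mols()$acetic
  expect_length(match_pattern(compile_smarts("O=C"), acetic), 1L)
  expect_length(match_pattern(compile_smarts("O-C"), acetic), 1L)
  expect_length(match_pattern(compile_smarts("O~C"), acetic), 2L)
  expect_length(match_pattern(compile_smarts("C#N"),
                              mol_from_smiles("CC#N")), 1L)
  # aromatic bond
  expect_length(match_pattern(compile_smarts("c:c"),
                              fix_mols()$benzene), 12L)
  # unsupported constructs are refused, not silently wrong
  expect_error(compile_smarts("[$(NC=O)]"), "recursive")
})

test_that("ring-closure patterns match whole rings", {
  p <- compile_smarts("c1ccccc1")
  expect_length(match_pattern(p, fix_mols()$benzene), 12L)  # automorphisms
  expect_length(match_pattern(p, fix_mols()$pyridine), 0L)
})

test_that("heavy-atom isomorphism distinguishes constitution, not atom order", {
  a <- mol_from_smiles("OC(=O)c1ccc(N)cc1")
  b <- mol_from_smiles("Nc1ccc(cc1)C(O)=O")
  expect_gt(length(heavy_isomorphisms(a, b)), 0L)
  c2 <- mol_from_smiles("OC(=O)c1ccccc1N")  # ortho isomer
  expect_length(heavy_isomorphisms(a, c2), 0L)
  expect_length(heavy_isomorphisms(fix_mols()$benzene,
                                   fix_mols()$pyridine), 0L)
})
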