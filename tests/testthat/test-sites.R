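# Structure edits, filters and the pattern oracle.

test_that("protonation adds one H and one positive charge at the site", {
  pyr <- fix_mols()$pyridine
  nidx <- which(pyr$atoms$element == "N") - 1L
  prot <- protonate_at(pyr, nidx)
  expect_identical(mol_net_charge(prot), 1L)
  expect_identical(prot$smiles, ob_canonical("c1cc[nH+]cc1"))
  expect_identical(sum(prot$atoms$element != "H"),
                   sum(pyr$atoms$element != "H"))
  expect_identical(n_atoms(prot), n_atoms(pyr) + 1L)

  water <- std_mol("O", "water")
  h3o <- protonate_at(water, 0L)
  expect_identical(h3o$atoms$charge[1], 1L)
  expect_identical(mol_net_charge(h3o), 1L)

  # carbon at full valence with no lone pair cannot accept a proton
  expect_error(protonate_at(std_mol("CC"), 0L), class = "site_edit_error")
})

test_that("deprotonation removes one H and one unit of charge", {
  ac <- fix_mols()$acetic
  oh <- which(ac$atoms$element == "O" &
                vapply(seq_len(n_atoms(ac)), function(i)
                  atom_total_h(ac, i) > 0, TRUE))[1] - 1L
  dep <- deprotonate_at(ac, oh)
  expect_identical(mol_net_charge(dep), -1L)
  expect_identical(dep$smiles, ob_canonical("CC(=O)[O-]"))
  # benzene C-H gives a structurally valid carbanion record
  phe_anion <- deprotonate_at(fix_mols()$benzene, 0L)
  expect_identical(mol_net_charge(phe_anion), -1L)
  # carbonyl O bears no H
  co <- which(ac$atoms$element == "O" &
                vapply(seq_len(n_atoms(ac)), function(i)
                  atom_total_h(ac, i) == 0, TRUE))[1] - 1L
  expect_error(deprotonate_at(ac, co), class = "site_edit_error")
})

test_that("structural-change filter accepts proton moves and rejects rearrangements", {
  pyr <- fix_mols()$pyridine
  nidx <- which(pyr$atoms$element == "N") - 1L
  prot <- protonate_at(pyr, nidx)
  expect_true(structural_change_filter(pyr, prot, "protonation"))

  # ring-opened putative product of the same formula/charge
  ring_open <- standardize(mol_from_smiles("C=CC=CC=N", "open"))
  ro_prot <- protonate_at(ring_open, which(ring_open$atoms$element == "N") - 1L)
  expect_false(structural_change_filter(pyr, ro_prot, "protonation"))

  # heavy-atom count change
  bigger <- protonate_at(std_mol("Cc1ccncc1"), 4L)
  expect_false(structural_change_filter(pyr, bigger, "protonation"))

  # charge bookkeeping must match the reaction direction
  expect_false(structural_change_filter(pyr, prot, "deprotonation"))
})

test_that("energy-window filter keeps candidates within 10 eV inclusive", {
  mk <- function(rel) list(atom_index = 0L, reaction = "protonation",
                           product = NULL, rel_energy_ev = rel)
  cands <- lapply(c(0, 5.0, 9.9), mk)
  expect_length(energy_window_filter(cands), 3L)
  cands <- lapply(c(0, 10.0, 10.01), mk)
  kept <- energy_window_filter(cands)
  expect_length(kept, 2L)
  expect_identical(vapply(kept, `[[`, 0, "rel_energy_ev"), c(0, 10.0))
  expect_length(energy_window_filter(lapply(0, mk)), 1L)
  expect_length(energy_window_filter(list()), 0L)
})

test_that("site candidates carry relative energies anchored at zero", {
  pyr <- fix_mols()$pyridine
  cands <- site_candidates(pyr, 0:(n_atoms(pyr) - 1L), "deprotonation")
  rel <- vapply(cands, `[[`, 0, "rel_energy_ev")
  expect_true(all(rel >= 0))
  # symmetry-equivalent sites share the minimum, so at least one sits at 0
  expect_gte(sum(rel == 0), 1L)
})

test_that("oracle labels canonical acidic/basic groups and nothing on ethane", {
  pats <- load_patterns()
  pyr_lab <- oracle_label(fix_mols()$pyridine, pats)
  nidx <- which(fix_mols()$pyridine$atoms$element == "N")
  expect_identical(which(pyr_lab$protonation$labels == 1L), nidx)
  expect_identical(sum(pyr_lab$deprotonation$labels), 0L)

  phe_lab <- oracle_label(fix_mols()$phenol, pats)
  oidx <- which(fix_mols()$phenol$atoms$element == "O")
  expect_identical(which(phe_lab$deprotonation$labels == 1L), oidx)

  eth_lab <- oracle_label(std_mol("CC"), pats)
  expect_identical(sum(eth_lab$protonation$labels), 0L)
  expect_identical(sum(eth_lab$deprotonation$labels), 0L)
})

test_that("oracle labels only H-bearing atoms for deprotonation and edits round-trip", {
  pats <- load_patterns()
  for (m in list(fix_mols()$paba, fix_mols()$acetic, fix_mols()$phenol)) {
    ol <- oracle_label(m, pats)
    det <- attr(ol, "sites")
    for (k in seq_len(nrow(det))) {
      a0 <- det$atom_index[k]
      if (det$reaction[k] == "deprotonation") {
        expect_gte(atom_total_h(m, a0 + 1L), 1L)
        # edit -> edit back restores the parent canonical SMILES
        child <- deprotonate_at(m, a0)
        back <- protonate_at(child, a0)
        expect_identical(back$smiles, m$smiles)
      } else {
        child <- protonate_at(m, a0)
        back <- deprotonate_at(child, a0)
        expect_identical(back$smiles, m$smiles)
      }
    }
  }
})

test_that("amide nitrogens are not labelled basic", {
  para <- std_mol("CC(=O)Nc1ccc(O)cc1", "paracetamol")
  ol <- oracle_label(para)
  det <- attr(ol, "sites")
  n_rows <- det[det$reaction == "protonation", ]
  amide_n <- which(para$atoms$element == "N") - 1L
  expect_false(amide_n %in% n_rows$atom_index)
})
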