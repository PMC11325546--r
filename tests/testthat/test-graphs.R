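# Feature schema lock, graph featurization, molecular descriptors, pair
# construction.

test_that("the node-feature schema is locked at exactly 61 features", {
  sch <- feature_schema()
  expect_identical(sum(sch$node_blocks), 61L)
  expect_identical(sch$n_node_features, 61L)
  expect_length(schema_feature_names(sch, "node"), 61L)
  # every named semiempirical/topological feature has a slot
  nm <- names(sch$node_blocks)
  expect_true(all(c("atom_type", "formal_charge", "degree", "total_h",
                    "hybridization", "aromatic", "in_ring", "is_hbd",
                    "is_hba", "xtb_partial_charge", "xtb_fukui_plus",
                    "xtb_fukui_zero", "xtb_fukui_minus", "xtb_coord_number",
                    "xtb_alpha") %in% nm))
  expect_true(all(c("bond_type", "conjugated", "in_ring", "wiberg") %in%
                    names(sch$edge_blocks)))
  expect_identical(names(sch$mol_blocks),
                   c("RadiusOfGyration", "Eccentricity", "Spherocity",
                     "FractionCSP3", "Asphericity", "xTB-Energy"))
  expect_identical(schema_feature_names(sch, "edge")[1], "bond_type:SINGLE")
})

test_that("featurize produces a (N x 61) matrix with symmetric arcs and finite values", {
  eth <- fix_mols()$ethanol
  g <- featurize(eth, compute_qm(eth))
  expect_identical(dim(g$x), c(9L, 61L))  # ethanol with explicit H
  expect_identical(ncol(g$edge_index), 16L)  # 8 bonds, both directions
  expect_true(all(is.finite(g$x)))
  # every directed arc has its reverse with identical features
  key <- paste(g$edge_index[1, ], g$edge_index[2, ])
  rev_key <- paste(g$edge_index[2, ], g$edge_index[1, ])
  expect_setequal(key, rev_key)
  for (k in seq_along(key)) {
    kr <- which(key == rev_key[k])[1]
    expect_identical(g$edge_attr[k, ], g$edge_attr[kr, ])
  }
})

test_that("featurize rejects misaligned QM features and names bad blocks", {
  eth <- fix_mols()$ethanol
  qm <- compute_qm(eth)
  short <- qm; short$partial_charge <- short$partial_charge[-1]
  expect_error(featurize(eth, short), "misaligned")
  bad <- qm; bad$polarizability[2] <- NaN
  expect_error(featurize(eth, bad), "xtb_alpha")
})

test_that("shape descriptors obey their degenerate-case contracts", {
  # planar arrangement -> Spherocity 0
  flat <- fix_mols()$benzene
  flat$coords[, 3] <- 0
  d <- molecular_descriptors(flat)
  expect_equal(unname(d["Spherocity"]), 0, tolerance = 1e-10)

  expect_equal(unname(molecular_descriptors(std_mol("C"))["FractionCSP3"]), 1)

  # perfectly linear triatomic: maximal asphericity, eccentricity 1
  lin <- std_mol("C")  # reuse any record, overwrite coordinates
  lin <- mol_new(data.frame(element = c("O", "C", "O"), charge = 0L,
                            nH = 0L, aromatic = FALSE, chiral = 0L),
                 data.frame(i = c(1, 2), j = c(2, 3), order = c(2, 2)),
                 id = "co2")
  lin$coords <- cbind(c(-1.16, 0, 1.16), 0, 0)
  d <- molecular_descriptors(lin)
  expect_equal(unname(d["Asphericity"]), 1, tolerance = 1e-10)
  expect_equal(unname(d["Eccentricity"]), 1, tolerance = 1e-10)

  # single atom: all shape descriptors zero, not NaN
  atom <- mol_new(data.frame(element = "O", charge = 0L, nH = 0L,
                             aromatic = FALSE, chiral = 0L),
                  data.frame(i = integer(), j = integer(),
                             order = numeric()), id = "o")
  atom$coords <- matrix(0, 1, 3)
  expect_true(all(is.finite(molecular_descriptors(atom))))
})

test_that("enantiomer graphs are identical feature-for-feature", {
  ala <- fix_mols()$alanine
  ent <- invert_stereocenters(ala)
  ga <- featurize(ala, compute_qm(ala))
  ge <- featurize(ent, compute_qm(ent))
  expect_equal(ga$x, ge$x, tolerance = 1e-12)
  expect_equal(ga$edge_attr, ge$edge_attr, tolerance = 1e-12)
  expect_equal(ga$mol_features, ge$mol_features, tolerance = 1e-12)
})

test_that("atom permutation of the input permutes features consistently", {
  a <- std_mol("OC(=O)c1ccc(N)cc1")
  b <- std_mol("Nc1ccc(cc1)C(O)=O")  # same molecule entered differently
  ga <- featurize(a, compute_qm(a))
  gb <- featurize(b, compute_qm(b))
  expect_identical(ga$x, gb$x)  # canonical ordering makes them equal
})

test_that("pair featurization shares the protonation energy and enforces the filter", {
  ac <- fix_mols()$acetic
  oh <- which(ac$atoms$element == "O" &
                vapply(seq_len(n_atoms(ac)), function(i)
                  atom_total_h(ac, i) > 0, TRUE))[1] - 1L
  dep <- deprotonate_at(ac, oh)
  pair <- featurize_pair(list(mol = ac, qm = compute_qm(ac)),
                         list(mol = dep, qm = compute_qm(dep)))
  expect_identical(pair$graph_prot$n_atoms, pair$graph_deprot$n_atoms + 1L)
  e1 <- pair$graph_prot$mol_features[["xTB-Energy"]]
  expect_identical(e1, pair$graph_deprot$mol_features[["xTB-Energy"]])
  expect_equal(e1, compute_qm(ac)$total_energy - compute_qm(dep)$total_energy)

  # unrelated molecules are rejected
  expect_error(
    featurize_pair(list(mol = ac, qm = compute_qm(ac)),
                   list(mol = fix_mols()$benzene,
                        qm = compute_qm(fix_mols()$benzene))),
    "exactly one proton")
})
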