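# Synthetic generator: determinism, filters by construction, label
# function recovery, benchmark disjointness.

test_that("the generator is deterministic and outputs pass every filter", {
  spec <- synthetic_spec(25, seed = 7, noise_sd = 0)
  a <- gen_library(spec)
  b <- gen_library(spec)
  expect_identical(vapply(a, `[[`, "", "smiles"),
                   vapply(b, `[[`, "", "smiles"))
  expect_true(all(vapply(a, element_filter, TRUE)))
  expect_true(all(vapply(a, function(m) mol_net_charge(m) == 0L, TRUE)))
  expect_length(unique(vapply(a, `[[`, "", "smiles")), 25L)
  expect_length(gen_library(synthetic_spec(0, seed = 1)), 0L)
})

test_that("labels are deterministic, clipped to [0, 14], and phenols are labelled on the hydroxyl", {
  spec <- synthetic_spec(15, seed = 3, noise_sd = 0.3)
  mols <- gen_library(spec)
  for (m in mols[1:5]) {
    l1 <- assign_labels(m, spec)
    l2 <- assign_labels(m, spec)
    expect_identical(l1$pka_map, l2$pka_map)
    if (length(l1$pka_map))
      expect_true(all(pka_range_filter(l1$pka_map)))
  }
  phe <- std_mol("Oc1ccccc1", "phenol")
  al <- assign_labels(phe, spec)
  det <- al$detail
  expect_identical(det$class[det$reaction == "deprotonation"], "phenol")
  expect_identical(det$atom_index[det$reaction == "deprotonation"],
                   which(phe$atoms$element == "O") - 1L)
})

test_that("noiseless labels are recovered exactly by a linear probe on the generator features", {
  spec <- synthetic_spec(60, seed = 13, noise_sd = 0)
  mols <- gen_library(spec)
  rows <- list()
  for (m in mols) {
    d <- assign_labels(m, spec)$detail
    if (!is.null(d) && nrow(d)) rows[[length(rows) + 1L]] <- d
  }
  d <- do.call(rbind, rows)
  # pKa may be clipped at the range ends; regress on the interior points
  d <- d[d$pka > 0 & d$pka < 14, ]
  fit <- stats::lm(pka ~ 0 + class + n_halo + aromatic_attach + in_ring,
                   data = d)
  # exact linearity: the generator leaks no signal beyond its stated terms
  expect_lt(max(abs(stats::residuals(fit))), 1e-6)
  cf <- stats::coef(fit)
  lp <- spec$label_params
  expect_equal(unname(cf["n_halo"]), lp$halo_2bond, tolerance = 1e-6)
  expect_equal(unname(cf["in_ring"]), lp$in_ring, tolerance = 1e-6)
  # aromatic attachment can be constant within every class in a given draw
  # (perfect collinearity with the class intercepts); recover accordingly
  seen <- sub("^class", "", names(cf)[startsWith(names(cf), "class")])
  base_hat <- cf[paste0("class", seen)]
  if (is.na(cf["aromatic_attach"])) {
    arom_const <- vapply(split(d$aromatic_attach, d$class),
                         function(v) unique(v)[1], 0)[seen]
    expect_equal(unname(base_hat),
                 unname(lp$base[seen] + lp$aromatic_attach * arom_const),
                 tolerance = 1e-6)
  } else {
    expect_equal(unname(cf["aromatic_attach"]), lp$aromatic_attach,
                 tolerance = 1e-6)
    expect_equal(unname(base_hat), unname(lp$base[seen]), tolerance = 1e-6)
  }
})

test_that("weak and experimental labels differ by the documented offset when noiseless", {
  base <- default_label_params()
  shifted <- base; shifted$offset <- 0.6
  sw <- synthetic_spec(10, seed = 17, noise_sd = 0, label_params = base)
  se <- synthetic_spec(10, seed = 17, noise_sd = 0, label_params = shifted)
  mols <- gen_library(sw)
  for (m in mols[1:4]) {
    lw <- assign_labels(m, sw)$detail
    le <- assign_labels(m, se)$detail
    if (is.null(lw) || nrow(lw) == 0L) next
    interior <- lw$pka > 0 & lw$pka < 14 & le$pka > 0 & le$pka < 14
    expect_equal(le$pka[interior] - lw$pka[interior],
                 rep(0.6, sum(interior)), tolerance = 1e-9)
  }
})

test_that("benchmark sets are disjoint by molecule and carry a manifest", {
  lp_exp <- default_label_params(); lp_exp$offset <- 0.6
  bm <- make_benchmark(synthetic_spec(30, seed = 1, noise_sd = 0),
                       synthetic_spec(15, seed = 2, noise_sd = 0,
                                      label_params = lp_exp))
  weak_ids <- unique(vapply(bm$weak, `[[`, "", "mol_id"))
  weak_smiles <- unique(vapply(bm$weak, function(p) p$graph_deprot$smiles, ""))
  exp_smiles <- unique(vapply(bm$exp, function(p) p$graph_deprot$smiles, ""))
  # molecule-level disjointness (the deprotonated branch of a basic pair is
  # the parent molecule; acidic parents are the protonated branch)
  exp_parents <- unique(c(
    vapply(bm$exp, function(p)
      if (p$reaction == "acidic") p$graph_prot$smiles else
        p$graph_deprot$smiles, "")))
  weak_parents <- unique(c(
    vapply(bm$weak, function(p)
      if (p$reaction == "acidic") p$graph_prot$smiles else
        p$graph_deprot$smiles, "")))
  expect_length(intersect(exp_parents, weak_parents), 0L)
  expect_identical(bm$manifest$weak$seed, 1L)
  expect_identical(bm$manifest$exp$offset, 0.6)
  # regenerating from the manifest reproduces the datasets
  bm2 <- make_benchmark(synthetic_spec(bm$manifest$weak$n_molecules,
                                       seed = bm$manifest$weak$seed,
                                       noise_sd = bm$manifest$weak$noise_sd),
                        synthetic_spec(bm$manifest$exp$n_molecules,
                                       seed = bm$manifest$exp$seed,
                                       noise_sd = bm$manifest$exp$noise_sd,
                                       label_params = lp_exp))
  expect_identical(vapply(bm2$weak, `[[`, 0, "target_pka"),
                   vapply(bm$weak, `[[`, 0, "target_pka"))
})

test_that("the one-site-per-reaction convention keeps the most stable site", {
  spec <- synthetic_spec(10, seed = 23, noise_sd = 0)
  mols <- gen_library(spec)
  ds_all <- make_pair_dataset(mols[1:5], spec, all_sites = TRUE)
  ds_one <- make_pair_dataset(mols[1:5], spec)
  per_mol <- table(vapply(ds_one, `[[`, "", "mol_id"),
                   vapply(ds_one, `[[`, "", "reaction"))
  expect_true(all(per_mol <= 1L))
  expect_lte(length(ds_one), length(ds_all))
})
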