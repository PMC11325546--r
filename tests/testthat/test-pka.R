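# Pair building, the regression model's contracts, metrics, Tanimoto,
# integrated gradients.

test_that("build_pairs follows the acidic/basic conventions", {
  ac <- fix_mols()$acetic
  ol <- oracle_label(ac)
  pairs <- build_pairs(ac, ol)
  expect_length(pairs, 1L)
  expect_identical(pairs[[1]]$reaction, "acidic")
  expect_identical(pairs[[1]]$graph_prot$n_atoms,
                   pairs[[1]]$graph_deprot$n_atoms + 1L)
  # the neutral acid is the protonated branch
  expect_identical(pairs[[1]]$graph_prot$smiles, ac$smiles)

  pyr <- fix_mols()$pyridine
  pp <- build_pairs(pyr, oracle_label(pyr))
  expect_length(pp, 1L)
  expect_identical(pp[[1]]$reaction, "basic")
  expect_identical(pp[[1]]$graph_prot$smiles, ob_canonical("c1cc[nH+]cc1"))
  expect_identical(pp[[1]]$graph_deprot$smiles, pyr$smiles)

  # no labels -> no pairs
  empty <- build_pairs(std_mol("CC"), oracle_label(std_mol("CC")))
  expect_length(empty, 0L)
})

test_that("evaluate computes RMSE, MAE and coefficient of determination", {
  m <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_identical(c(m$rmse, m$mae, m$r2), c(0, 0, 1))
  m <- evaluate(c(2, 3, 4), c(1, 2, 3))
  expect_equal(c(m$rmse, m$mae), c(1, 1))
  # constant prediction at the mean gives R2 = 0
  m <- evaluate(rep(2, 3), c(1, 2, 3))
  expect_equal(m$r2, 0)
  # zero-variance truths flagged, not NaN
  m <- evaluate(c(1, 2), c(5, 5))
  expect_true(is.na(m$r2))
  expect_identical(attr(m$r2, "reason"), "zero-variance truths")
  expect_error(evaluate(1:3, 1:2), "equal length")
  expect_error(evaluate(numeric(0), numeric(0)), "non-empty")
})

test_that("tanimoto matches the set definition and max_tanimoto brackets it", {
  a <- c(1, 1, 0, 1, 0) > 0
  b <- c(1, 0, 1, 1, 1) > 0  # |intersection| = 2, |union| = 5
  expect_equal(tanimoto(a, b), 0.4)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, rep(FALSE, 5) | c(0, 0, 1, 0, 1)), 0)

  ms <- fix_mols()
  expect_equal(max_tanimoto(ms$benzene, list(ms$benzene, ms$ethanol)), 1)
  t <- max_tanimoto(ms$phenol, list(ms$ethanol))
  expect_lt(t, 0.8)  # dissimilar pair sits below the overlap threshold
})

test_that("model training is deterministic and prediction is stable", {
  fx <- fix_tiny_models()
  cfg <- pka_model_config(n_layers = 2L, hidden = 16L, head_hidden = c(16L),
                          batch_size = 64L, max_epochs = 10L,
                          patience = 5L, seed = 1L)
  plan <- train_plan(pretrain_epochs = 10L, patience = 5L, seed = 1L)
  m1 <- pretrain(pka_model_init(cfg), fx$pairs, plan)
  m2 <- pretrain(pka_model_init(cfg), fx$pairs, plan)
  expect_identical(m1$provenance$pretrain$best_val,
                   m2$provenance$pretrain$best_val)
  expect_identical(m1$history$pretrain$val_loss, m2$history$pretrain$val_loss)
  p1 <- forward(m1, fx$pairs[[1]])
  expect_identical(p1, forward(m1, fx$pairs[[1]]))  # eval determinism
  expect_identical(p1, forward(m2, fx$pairs[[1]]))
})

test_that("finetune requires a trained model and 0 epochs is a no-op on weights", {
  fx <- fix_tiny_models()
  cfg <- pka_model_config(seed = 1L)
  expect_error(finetune(pka_model_init(cfg), fx$pairs, train_plan()),
               "pretrain")
  m <- fx$pka
  m0 <- finetune(m, fx$pairs, train_plan(finetune_epochs = 0L))
  expect_identical(m0$params, m$params)
})

test_that("early stopping halts when validation loss stops improving", {
  fx <- fix_tiny_models()
  cfg <- pka_model_config(n_layers = 2L, hidden = 16L, head_hidden = c(16L),
                          batch_size = 64L, max_epochs = 200L,
                          patience = 5L, seed = 2L)
  m <- pretrain(pka_model_init(cfg), fx$pairs,
                train_plan(pretrain_epochs = 200L, patience = 5L, seed = 2L))
  h <- m$history$pretrain
  expect_lt(nrow(h), 200L)
  expect_lte(nrow(h) - m$provenance$pretrain$best_epoch, 5L)
})

test_that("model save/load round-trips weights and predictions exactly", {
  fx <- fix_tiny_models()
  f <- withr::local_tempfile(fileext = ".json")
  save_model(fx$pka, f)
  back <- load_model(f)
  expect_s3_class(back, "pka_model")
  expect_identical(back$schema_hash, fx$pka$schema_hash)
  expect_equal(predict_pka(back, fx$pairs[1:3]),
               predict_pka(fx$pka, fx$pairs[1:3]), tolerance = 1e-12)

  f2 <- withr::local_tempfile(fileext = ".json")
  save_model(fx$sites_prot, f2)
  sm <- load_model(f2)
  g <- fx$pairs[[1]]$graph_deprot
  expect_equal(attr(predict_sites(sm, g), "prob"),
               attr(predict_sites(fx$sites_prot, g), "prob"),
               tolerance = 1e-12)
})

test_that("site predictions have length N and obey threshold semantics", {
  fx <- fix_tiny_models()
  g <- featurize(fx$mols[[1]], compute_qm(fx$mols[[1]]))
  lab <- predict_sites(fx$sites_prot, g)
  expect_length(lab$labels, g$n_atoms)
  expect_true(all(lab$labels %in% 0:1))
  prob <- attr(lab, "prob")
  all_on <- predict_sites(fx$sites_prot, g, threshold = 0)
  expect_identical(all_on$labels, as.integer(prob > 0))
  # schema mismatch is refused
  g2 <- g; g2$schema_hash <- g$schema_hash + 1L
  expect_error(predict_sites(fx$sites_prot, g2), "schema")
})

test_that("integrated gradients: zero at the input baseline, completeness on a trained model", {
  fx <- fix_tiny_models()
  # pick a probe pair whose output differs clearly from the zero-baseline
  # output, so the relative completeness bound is meaningful
  base_pred <- vapply(fx$pairs[1:8], function(p) {
    b <- p
    b$graph_prot$x[] <- 0; b$graph_prot$edge_attr[] <- 0
    b$graph_prot$mol_features[] <- 0
    b$graph_deprot$x[] <- 0; b$graph_deprot$edge_attr[] <- 0
    b$graph_deprot$mol_features[] <- 0
    abs(forward(fx$pka, p) - forward(fx$pka, b))
  }, 0)
  pair <- fx$pairs[[which.max(base_pred)]]
  ig0 <- integrated_gradients(fx$pka, pair, baseline = pair, steps = 4L)
  expect_equal(ig0$total, 0, tolerance = 1e-12)
  ig <- integrated_gradients(fx$pka, pair, steps = 128L)
  gap <- ig$f_input - ig$f_baseline
  expect_equal(ig$total, gap, tolerance = abs(gap) * 0.01)
  # block aggregation covers all features
  agg <- ig_by_feature(ig)
  expect_identical(nrow(agg), 61L + 7L + 6L)
  expect_equal(sum(agg$attribution), ig$total, tolerance = 1e-9)
})

test_that("enantiomer pairs predict identical pKa through the model", {
  fx <- fix_tiny_models()
  ala <- std_mol("N[C@@H](C)C(=O)O", "ala")
  ent <- invert_stereocenters(ala)
  p1 <- build_pairs(ala, oracle_label(ala))
  p2 <- build_pairs(ent, oracle_label(ent))
  expect_identical(length(p1), length(p2))
  expect_equal(predict_pka(fx$pka, p1), predict_pka(fx$pka, p2),
               tolerance = 1e-6)
})
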