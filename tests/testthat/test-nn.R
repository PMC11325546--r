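# Network engine: analytic gradients versus finite differences, batching,
# optimizer determinism, split fractions.

random_graph <- function(n, seed) {
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * 61), n, 61)
    edges <- cbind(1:(n - 1), 2:n)
    if (n > 3) edges <- rbind(edges, c(1, n))
    ei <- rbind(c(edges[, 1], edges[, 2]), c(edges[, 2], edges[, 1]))
    ne <- nrow(edges)
    ea1 <- matrix(stats::rnorm(ne * 7), ne, 7)
    structure(list(x = x, edge_index = ei, edge_attr = rbind(ea1, ea1),
                   mol_features = stats::rnorm(6), n_atoms = n,
                   schema_hash = feature_schema()$hash, id = paste0("g", n),
                   smiles = ""), class = "mol_graph")
  })
}

num_grad <- function(f, params, path, i, j, eps = 1e-5) {
  poke <- function(p, path, val) {
    if (length(path) == 1L) { p[[path[[1]]]] <- val; return(p) }
    p[[path[[1]]]] <- poke(p[[path[[1]]]], path[-1], val)
    p
  }
  m <- Reduce(`[[`, path, params)
  m[i, j] <- m[i, j] + eps
  lp <- f(poke(params, path, m))
  m[i, j] <- m[i, j] - 2 * eps
  lm <- f(poke(params, path, m))
  (lp - lm) / (2 * eps)
}

test_that("analytic gradients match finite differences for all three GNN families", {
  B <- batch_graphs(lapply(c(4, 5, 6), random_graph, seed = 11))
  labels <- with_seed(3, stats::rbinom(B$n_nodes, 1, 0.3))
  for (fam in c("gcn", "gat", "gtr")) {
    config <- list(family = fam, n_layers = 2L, hidden = 6L, task = "node",
                   n_node_features = 61L, n_edge_features = 7L,
                   n_mol_features = 6L)
    params <- nn_init(config, seed = 4)
    f <- function(p) nn_node_pass(p, B, config, labels = labels,
                                  pos_weight = 2)$loss
    res <- nn_node_pass(params, B, config, labels = labels, pos_weight = 2,
                        want_grad = TRUE)
    checks <- list(list(path = list("enc", 1L, "W"),
                        g = res$grads$enc[[1]]$W),
                   list(path = list("enc", 2L, "We"),
                        g = res$grads$enc[[2]]$We),
                   list(path = list("head", "W1"), g = res$grads$head$W1))
    if (fam == "gat")
      checks <- c(checks, list(list(path = list("enc", 1L, "a_src"),
                                    g = res$grads$enc[[1]]$a_src)))
    if (fam == "gtr")
      checks <- c(checks, list(list(path = list("enc", 1L, "Wq"),
                                    g = res$grads$enc[[1]]$Wq)))
    for (chk in checks) {
      ij <- with_seed(7, c(sample(nrow(chk$g), 1), sample(ncol(chk$g), 1)))
      ng <- num_grad(f, params, chk$path, ij[1], ij[2])
      expect_equal(chk$g[ij[1], ij[2]], ng, tolerance = 1e-4,
                   label = paste(fam, paste(unlist(chk$path), collapse = "/")))
    }
  }
})

test_that("pair-task gradients (shared encoder) match finite differences", {
  Bp <- batch_graphs(lapply(c(5, 6), random_graph, seed = 21))
  Bd <- batch_graphs(lapply(c(4, 5), random_graph, seed = 22))
  targets <- c(4.2, 9.1)
  config <- list(family = "gcn", n_layers = 2L, hidden = 6L, task = "pair",
                 head_hidden = c(8L), n_node_features = 61L,
                 n_edge_features = 7L, n_mol_features = 6L)
  params <- nn_init(config, seed = 5)
  f <- function(p) nn_pair_pass(p, Bp, Bd, config, targets = targets)$loss
  res <- nn_pair_pass(params, Bp, Bd, config, targets = targets,
                      want_grad = TRUE)
  for (chk in list(list(path = list("enc", 1L, "W"),
                        g = res$grads$enc[[1]]$W),
                   list(path = list("head", "Wout"),
                        g = res$grads$head$Wout))) {
    ij <- with_seed(9, c(sample(nrow(chk$g), 1), sample(ncol(chk$g), 1)))
    ng <- num_grad(f, params, chk$path, ij[1], ij[2])
    expect_equal(chk$g[ij[1], ij[2]], ng, tolerance = 1e-4)
  }
})

test_that("input-feature gradients back out to the node/edge/mol inputs", {
  Bp <- batch_graphs(lapply(c(5, 6), random_graph, seed = 31))
  Bd <- batch_graphs(lapply(c(4, 5), random_graph, seed = 32))
  config <- list(family = "gcn", n_layers = 2L, hidden = 6L, task = "pair",
                 head_hidden = c(8L), n_node_features = 61L,
                 n_edge_features = 7L, n_mol_features = 6L)
  params <- nn_init(config, seed = 6)
  gr <- nn_pair_pass(params, Bp, Bd, config, want_input_grad = TRUE)$input_grads
  eps <- 1e-5
  probe <- function(field, i, j, got) {
    B2 <- Bp
    B2[[field]][i, j] <- B2[[field]][i, j] + eps
    up <- sum(nn_pair_pass(params, B2, Bd, config)$pred)
    B2[[field]][i, j] <- B2[[field]][i, j] - 2 * eps
    dn <- sum(nn_pair_pass(params, B2, Bd, config)$pred)
    expect_equal(got, (up - dn) / (2 * eps), tolerance = 1e-4)
  }
  probe("x", 3, 10, gr$x_prot[3, 10])
  probe("edge_attr", 2, 5, gr$e_prot[2, 5])
  probe("mol_features", 1, 4, gr$mol_prot[1, 4])
})

test_that("batching is block-diagonal: batched output equals per-graph output", {
  gs <- lapply(c(4, 6, 5), random_graph, seed = 41)
  config <- list(family = "gcn", n_layers = 2L, hidden = 6L, task = "node",
                 n_node_features = 61L, n_edge_features = 7L,
                 n_mol_features = 6L)
  params <- nn_init(config, seed = 8)
  all_prob <- nn_node_pass(params, batch_graphs(gs), config)$prob
  solo <- unlist(lapply(gs, function(g)
    nn_node_pass(params, batch_graphs(list(g)), config)$prob))
  expect_equal(all_prob, solo, tolerance = 1e-12)
})

test_that("molecule-level splits give 80:10:10 and never share molecules", {
  ids <- rep(sprintf("m%03d", 1:100), each = 3)  # 3 sites per molecule
  sp <- split_by_molecule(ids, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(length(sp$train) + length(sp$val) + length(sp$test),
                   length(ids))
  expect_identical(length(unique(ids[sp$train])), 80L)
  expect_identical(length(unique(ids[sp$val])), 10L)
  expect_identical(length(unique(ids[sp$test])), 10L)
  expect_length(intersect(ids[sp$train], ids[sp$test]), 0L)
  expect_length(intersect(ids[sp$train], ids[sp$val]), 0L)
})
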