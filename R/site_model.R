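# Node-classification models for reaction-site enumeration. One model per
# reaction (protonation / deprotonation), trained on oracle-labelled graphs
# with a positive-class-weighted binary cross-entropy (most atoms are not
# sites) and early stopping on validation loss.

#' Default site-model configuration
#'
#' @param family GNN family: `"gcn"`, `"gat"` or `"gtr"`.
#' @param n_layers,hidden Encoder depth and width.
#' @param lr,batch_size,max_epochs,patience Optimization settings.
#' @param threshold Classification threshold on the predicted probability.
#' @param seed Seed controlling initialization and batch order.
#' @return Config list.
#' @export
site_model_config <- function(family = "gcn", n_layers = 3L, hidden = 48L,
                              lr = 5e-3, batch_size = 64L,
                              max_epochs = 60L, patience = 10L,
                              threshold = 0.5, seed = 0L) {
  sch <- feature_schema()
  list(family = family, n_layers = n_layers, hidden = hidden, lr = lr,
       batch_size = batch_size, max_epochs = max_epochs,
       patience = patience, threshold = threshold, seed = seed,
       task = "node", n_node_features = sch$n_node_features,
       n_edge_features = sch$n_edge_features,
       n_mol_features = sch$n_mol_features)
}

#' Train a reaction-site node classifier
#'
#' Splits the dataset 80:10:10 by molecule (never by atom), trains with
#' early stopping on validation loss, and reports held-out test accuracy.
#'
#' @param dataset List of examples: each `list(graph = mol_graph,
#'   labels = integer 0/1 vector of length n_atoms, id = molecule id)`.
#' @param config From [site_model_config()].
#' @param reaction Label for bookkeeping: `"protonation"` or
#'   `"deprotonation"`.
#' @return Object of class `site_model` with `params`, `config`, `history`,
#'   `schema_hash`, `reaction`, `metrics` (held-out accuracy etc.).
#' @export
train_site_model <- function(dataset, config = site_model_config(),
                             reaction = "protonation") {
  stopifnot(length(dataset) >= 3L)
  ids <- vapply(dataset, `[[`, "", "id")
  sp <- split_by_molecule(ids, c(0.8, 0.1, 0.1), seed = config$seed)
  if (length(sp$train) == 0L || length(sp$val) == 0L)
    stop("empty train or validation split")
  get_labels <- function(ex) {
    l <- ex$labels
    if (inherits(l, "site_label_set")) l <- l$labels
    as.integer(l)
  }
  ytr <- unlist(lapply(dataset[sp$train], get_labels))
  pos_weight <- max(1, sum(ytr == 0L) / max(1L, sum(ytr == 1L)))
  mk_batch <- function(idx) {
    list(B = batch_graphs(lapply(dataset[idx], `[[`, "graph")),
         y = unlist(lapply(dataset[idx], get_labels)))
  }
  vb <- mk_batch(sp$val)
  params <- nn_init(config, config$seed)
  batches <- lapply(make_minibatch_indices(sp$train, config$batch_size,
                                           config$seed), mk_batch)
  step_fn <- function(params, b) {
    r <- nn_node_pass(params, b$B, config, labels = b$y,
                      pos_weight = pos_weight, want_grad = TRUE)
    list(loss = r$loss, grads = r$grads)
  }
  val_fn <- function(params)
    nn_node_pass(params, vb$B, config, labels = vb$y,
                 pos_weight = pos_weight)$loss
  fit <- train_loop(params, batches, step_fn, val_fn, config)
  metrics <- list()
  if (length(sp$test) > 0L) {
    tb <- mk_batch(sp$test)
    pr <- nn_node_pass(fit$params, tb$B, config)$prob
    pred <- as.integer(pr >= config$threshold)
    metrics <- list(test_accuracy = mean(pred == tb$y),
                    test_n_atoms = length(tb$y),
                    test_n_molecules = length(sp$test))
  }
  structure(list(params = fit$params, config = config,
                 schema_hash = feature_schema()$hash,
                 reaction = reaction, history = fit$history,
                 best_val = fit$best_val, best_epoch = fit$best_epoch,
                 pos_weight = pos_weight, metrics = metrics,
                 seed = config$seed),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat(sprintf("<site_model %s: %s, %d layers x %d, best val loss %.4f (epoch %d)%s>\n",
              x$reaction, x$config$family, x$config$n_layers,
              x$config$hidden, x$best_val, x$best_epoch,
              if (!is.null(x$metrics$test_accuracy))
                sprintf(", test acc %.3f", x$metrics$test_accuracy) else ""))
  invisible(x)
}

#' Predict reaction sites for one molecule graph
#'
#' @param model A `site_model`.
#' @param graph A `mol_graph` (same feature schema).
#' @param threshold Probability threshold (default: the model's configured
#'   threshold). Labels are 1 where probability strictly exceeds the
#'   threshold when `threshold` is 0, and `>= threshold` otherwise.
#' @return `site_label_set` with attribute `"prob"` (per-atom
#'   probabilities).
#' @export
predict_sites <- function(model, graph, threshold = NULL) {
  if (!identical(graph$schema_hash, model$schema_hash))
    stop("feature schema hash mismatch between graph and model")
  threshold <- threshold %||% model$config$threshold
  B <- batch_graphs(list(graph))
  prob <- nn_node_pass(model$params, B, model$config)$prob
  labels <- if (threshold == 0) as.integer(prob > 0) else
    as.integer(prob >= threshold)
  structure(list(mol_id = graph$id, labels = labels,
                 reaction = model$reaction),
            class = "site_label_set", prob = prob)
}

#' Per-atom accuracy of a site model over a dataset
#' @keywords internal
site_model_accuracy <- function(model, dataset, threshold = NULL) {
  threshold <- threshold %||% model$config$threshold
  B <- batch_graphs(lapply(dataset, `[[`, "graph"))
  y <- unlist(lapply(dataset, function(ex) {
    l <- ex$labels
    if (inherits(l, "site_label_set")) l <- l$labels
    as.integer(l)
  }))
  prob <- nn_node_pass(model$params, B, model$config)$prob
  mean(as.integer(prob >= threshold) == y)
}
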