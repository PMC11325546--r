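# Paired-graph micro-pKa regression. Each example is the pair (protonated
# form, deprotonated form) of one reaction site; both graphs pass through a
# shared message-passing encoder, are mean-pooled, concatenated with the two
# molecular feature vectors and regressed to a single pKa by linear layers.
# Training follows the two-stage recipe: pretraining on a large weakly
# labelled corpus (80:10:10 molecule split), then transfer-learning
# fine-tuning on a small experimental-style set (80:20 split).

#' Build pair examples from site labels
#'
#' Acidic convention: the input molecule is the protonated form and the
#' deprotomer at each deprotonation-labelled atom is the partner. Basic
#' convention: the protomer at each protonation-labelled atom is the
#' protonated form and the input molecule the deprotonated one. Pairs whose
#' edit fails the structural-change filter are dropped with a warning.
#'
#' @param mol Standardized `mol_record` (the selected stable tautomer).
#' @param site_labels List with `protonation` and `deprotonation`
#'   `site_label_set`s (e.g. from [oracle_label()] or [predict_sites()]).
#' @param backend QM backend name.
#' @param schema Feature schema.
#' @param pka_map Optional named numeric vector `"<reaction>:<atom_index>"`
#'   -> target pKa used to fill `target_pka`.
#' @return List of `pair_example`s: `mol_id`, `atom_index` (0-based),
#'   `reaction` ("acidic"/"basic"), `graph_prot`, `graph_deprot`,
#'   `target_pka`.
#' @export
build_pairs <- function(mol, site_labels, backend = "mock",
                        schema = feature_schema(), pka_map = NULL) {
  qm_parent <- compute_qm(mol, backend)
  out <- list()
  add_pair <- function(atom0, reaction) {
    edit <- if (reaction == "acidic") deprotonate_at else protonate_at
    prod <- tryCatch(edit(mol, atom0), site_edit_error = function(e) NULL)
    if (is.null(prod)) {
      mp_log("warn", "pairs", sprintf("edit failed at atom %d (%s)", atom0,
                                      reaction), mol$id)
      return()
    }
    qm_prod <- compute_qm(prod, backend)
    pd <- if (reaction == "acidic")
      list(prot = list(mol = mol, qm = qm_parent),
           deprot = list(mol = prod, qm = qm_prod))
    else
      list(prot = list(mol = prod, qm = qm_prod),
           deprot = list(mol = mol, qm = qm_parent))
    gr <- tryCatch(featurize_pair(pd$prot, pd$deprot, schema),
                   error = function(e) NULL)
    if (is.null(gr)) {
      mp_log("warn", "pairs", sprintf(
        "pair at atom %d (%s) rejected by structural-change filter",
        atom0, reaction), mol$id)
      return()
    }
    key <- paste0(reaction, ":", atom0)
    out[[length(out) + 1L]] <<- structure(
      list(mol_id = mol$id, atom_index = atom0, reaction = reaction,
           graph_prot = gr$graph_prot, graph_deprot = gr$graph_deprot,
           target_pka = if (!is.null(pka_map) && key %in% names(pka_map))
             unname(pka_map[[key]]) else NA_real_),
      class = "pair_example")
  }
  for (a in which(site_labels$deprotonation$labels == 1L) - 1L)
    add_pair(a, "acidic")
  for (a in which(site_labels$protonation$labels == 1L) - 1L)
    add_pair(a, "basic")
  out
}

#' Default pKa-model configuration
#'
#' @inheritParams site_model_config
#' @param head_hidden Integer vector of linear-head layer widths.
#' @return Config list (`pooling` is fixed to global mean).
#' @export
pka_model_config <- function(family = "gcn", n_layers = 3L, hidden = 48L,
                             head_hidden = c(48L, 24L), lr = 5e-3,
                             batch_size = 256L, max_epochs = 100L,
                             patience = 15L, seed = 0L) {
  sch <- feature_schema()
  list(family = family, n_layers = n_layers, hidden = hidden,
       head_hidden = head_hidden, pooling = "mean", lr = lr,
       batch_size = batch_size, max_epochs = max_epochs,
       patience = patience, seed = seed, task = "pair",
       n_node_features = sch$n_node_features,
       n_edge_features = sch$n_edge_features,
       n_mol_features = sch$n_mol_features)
}

#' Training plan for the two-stage recipe
#'
#' @param pretrain_split Fractions for the weak-label stage (default
#'   80:10:10 by molecule).
#' @param finetune_split Train/validation fractions for fine-tuning
#'   (default 80:20).
#' @param lr_pretrain,lr_finetune Stage learning rates.
#' @param pretrain_epochs,finetune_epochs,patience Stage lengths.
#' @param seed Split/shuffle seed.
#' @return Plan list.
#' @export
train_plan <- function(pretrain_split = c(0.8, 0.1, 0.1),
                       finetune_split = c(0.8, 0.2),
                       lr_pretrain = 5e-3, lr_finetune = 1.5e-3,
                       pretrain_epochs = 100L, finetune_epochs = 80L,
                       patience = 15L, seed = 0L) {
  stopifnot(abs(sum(pretrain_split) - 1) < 1e-9,
            abs(sum(finetune_split) - 1) < 1e-9)
  list(pretrain_split = pretrain_split, finetune_split = finetune_split,
       lr_pretrain = lr_pretrain, lr_finetune = lr_finetune,
       pretrain_epochs = pretrain_epochs,
       finetune_epochs = finetune_epochs, patience = patience, seed = seed)
}

#' Initialize an untrained pKa model
#' @param config From [pka_model_config()].
#' @return Object of class `pka_model` (stage "init").
#' @export
pka_model_init <- function(config = pka_model_config()) {
  structure(list(params = nn_init(config, config$seed), config = config,
                 schema_hash = feature_schema()$hash, stage = "init",
                 y_center = 0, y_scale = 1,  # target normalization, set at
                 provenance = list(), history = list()),  # pretraining
            class = "pka_model")
}

#' @export
print.pka_model <- function(x, ...) {
  cat(sprintf("<pka_model: %s, %d layers x %d, head [%s], stage %s>\n",
              x$config$family, x$config$n_layers, x$config$hidden,
              paste(x$config$head_hidden, collapse = ","), x$stage))
  invisible(x)
}

pair_batches <- function(pairs) {
  list(Bp = batch_graphs(lapply(pairs, `[[`, "graph_prot")),
       Bd = batch_graphs(lapply(pairs, `[[`, "graph_deprot")),
       y = vapply(pairs, function(p) p$target_pka %||% NA_real_, 0))
}

# shared internal trainer for one stage
train_pka_stage <- function(model, pairs, idx_train, idx_val, lr,
                            max_epochs, patience, seed) {
  config <- model$config
  config$lr <- lr
  config$max_epochs <- max_epochs
  config$patience <- patience
  config$seed <- seed
  norm_y <- function(y) (y - model$y_center) / model$y_scale
  vb <- pair_batches(pairs[idx_val])
  vb$y <- norm_y(vb$y)
  batches <- lapply(make_minibatch_indices(idx_train, config$batch_size,
                                           config$seed),
                    function(ix) {
                      b <- pair_batches(pairs[ix])
                      b$y <- norm_y(b$y)
                      b
                    })
  step_fn <- function(params, b) {
    r <- nn_pair_pass(params, b$Bp, b$Bd, config, targets = b$y,
                      want_grad = TRUE)
    list(loss = r$loss, grads = r$grads)
  }
  val_fn <- function(params)
    nn_pair_pass(params, vb$Bp, vb$Bd, config, targets = vb$y)$loss
  train_loop(model$params, batches, step_fn, val_fn, config)
}

#' Pretrain the pKa model on a weak-label dataset
#'
#' @param model `pka_model` (stage "init" or later).
#' @param weak_dataset List of `pair_example`s with `target_pka` set.
#' @param plan From [train_plan()].
#' @return Pretrained `pka_model` (stage "pretrained") carrying training
#'   history and held-out test metrics in `provenance`.
#' @export
pretrain <- function(model, weak_dataset, plan = train_plan()) {
  stopifnot(inherits(model, "pka_model"), length(weak_dataset) >= 5L)
  ids <- vapply(weak_dataset, `[[`, "", "mol_id")
  sp <- split_by_molecule(ids, plan$pretrain_split, seed = plan$seed)
  if (length(sp$train) == 0L || length(sp$val) == 0L)
    stop("empty pretraining partition")
  ytr <- vapply(weak_dataset[sp$train], `[[`, 0, "target_pka")
  model$y_center <- mean(ytr)
  model$y_scale <- max(stats::sd(ytr), 1e-6)
  fit <- train_pka_stage(model, weak_dataset, sp$train, sp$val,
                         plan$lr_pretrain, plan$pretrain_epochs,
                         plan$patience, plan$seed)
  model$params <- fit$params
  model$stage <- "pretrained"
  model$history$pretrain <- fit$history
  test_metrics <- NULL
  if (length(sp$test) > 0L) {
    pred <- predict_pka(model, weak_dataset[sp$test])
    test_metrics <- evaluate(pred,
                             vapply(weak_dataset[sp$test], `[[`, 0,
                                    "target_pka"))
  }
  model$provenance$pretrain <- list(
    n_pairs = length(weak_dataset), seed = plan$seed,
    split = plan$pretrain_split, best_val = fit$best_val,
    best_epoch = fit$best_epoch, test_metrics = test_metrics)
  model
}

#' Fine-tune a pretrained pKa model on experimental-style labels
#'
#' Starts from the pretrained weights (error if the model was never
#' trained), splits 80:20 train/validation by molecule, and trains with a
#' reduced learning rate. `finetune_epochs = 0` returns the input model
#' unchanged (aside from provenance).
#'
#' @param model Pretrained `pka_model`.
#' @param experimental_dataset List of `pair_example`s with targets.
#' @param plan From [train_plan()].
#' @return Fine-tuned `pka_model` (stage "finetuned").
#' @export
finetune <- function(model, experimental_dataset, plan = train_plan()) {
  stopifnot(inherits(model, "pka_model"))
  if (identical(model$stage, "init"))
    stop("finetune requires a pretrained model; run pretrain() first")
  if (plan$finetune_epochs == 0L) {
    model$provenance$finetune <- list(n_pairs = length(experimental_dataset),
                                      epochs = 0L)
    return(model)
  }
  ids <- vapply(experimental_dataset, `[[`, "", "mol_id")
  sp <- split_by_molecule(ids, c(plan$finetune_split, 0), seed = plan$seed)
  if (length(sp$train) == 0L || length(sp$val) == 0L)
    stop("empty fine-tuning partition")
  fit <- train_pka_stage(model, experimental_dataset, sp$train, sp$val,
                         plan$lr_finetune, plan$finetune_epochs,
                         plan$patience, plan$seed)
  model$params <- fit$params
  model$stage <- "finetuned"
  model$history$finetune <- fit$history
  model$provenance$finetune <- list(
    n_pairs = length(experimental_dataset), seed = plan$seed,
    split = plan$finetune_split, best_val = fit$best_val,
    best_epoch = fit$best_epoch)
  model
}

#' Predict the micro-pKa of one pair example
#'
#' @param model A trained `pka_model`.
#' @param pair A `pair_example`.
#' @return Scalar predicted pKa (deterministic for fixed weights/input).
#' @export
forward <- function(model, pair) {
  predict_pka(model, list(pair))
}

#' Predict micro-pKa for a list of pair examples
#' @param model A trained `pka_model`.
#' @param pairs List of `pair_example`s.
#' @return Numeric vector of predictions.
#' @export
predict_pka <- function(model, pairs) {
  if (length(pairs) == 0L) return(numeric(0))
  hashes <- vapply(pairs, function(p) p$graph_prot$schema_hash, 0L)
  if (!all(hashes == model$schema_hash))
    stop("feature schema hash mismatch between pairs and model")
  b <- pair_batches(pairs)
  model$y_center +
    model$y_scale * nn_pair_pass(model$params, b$Bp, b$Bd, model$config)$pred
}

#' Regression metrics
#'
#' @param predictions,truths Equal-length non-empty numeric vectors.
#' @return List `rmse`, `mae`, `r2` (coefficient of determination;
#'   `NA` with attribute `"reason"` when the truths have zero variance).
#' @export
evaluate <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0L)
    stop("predictions and truths must be non-empty and equal length")
  err <- predictions - truths
  ss_tot <- sum((truths - mean(truths))^2)
  r2 <- if (ss_tot < 1e-12)
    structure(NA_real_, reason = "zero-variance truths") else
      1 - sum(err^2) / ss_tot
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)), r2 = r2,
       n = length(truths))
}

#' Tanimoto coefficient of two fingerprint bit sets
#' @param a,b Logical or 0/1 vectors of equal length.
#' @return |intersection| / |union| (1 if both are empty).
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

mol_fingerprint <- function(mol) {
  smi <- if (inherits(mol, "mol_record")) mol$smiles %||%
    canonical_smiles(mol) else mol
  ref <- ChemmineOB::forEachMol("SMILES", smi, identity)
  as.numeric(ChemmineOB::fingerprint_OB(ref, "FP2")) > 0
}

#' Maximum Tanimoto similarity of a query against a reference set
#'
#' Path-based (FP2, 1024-bit) fingerprints; used for train/test overlap
#' filtering at the 0.8 threshold.
#'
#' @param query `mol_record` (or SMILES string).
#' @param reference Non-empty list of `mol_record`s (or SMILES strings).
#' @return Maximum Tanimoto coefficient.
#' @export
max_tanimoto <- function(query, reference) {
  stopifnot(length(reference) >= 1L)
  fq <- mol_fingerprint(query)
  max(vapply(reference, function(r) tanimoto(fq, mol_fingerprint(r)), 0))
}

#' Integrated-gradients attribution for a pair example
#'
#' Midpoint Riemann approximation of the path integral of the model's
#' output gradient from `baseline` to the input, over node features, edge
#' features and molecular features of both graphs. Satisfies completeness:
#' the attributions sum to f(input) - f(baseline) as steps grow (exactly,
#' for a linear model).
#'
#' @param model A `pka_model`.
#' @param pair Input `pair_example`.
#' @param baseline Baseline `pair_example` of identical shapes; default:
#'   the input with all features zeroed.
#' @param steps Number of integration steps (>= 1).
#' @return List of attribution matrices (`x_prot`, `x_deprot`, `e_prot`,
#'   `e_deprot`, `mol_prot`, `mol_deprot`) plus `f_input`, `f_baseline`,
#'   `total` (= sum of all attributions).
#' @export
integrated_gradients <- function(model, pair, baseline = NULL, steps = 128L) {
  stopifnot(steps >= 1L)
  zero_graph <- function(g) {
    g$x[] <- 0; g$edge_attr[] <- 0; g$mol_features[] <- 0
    g
  }
  if (is.null(baseline)) {
    baseline <- pair
    baseline$graph_prot <- zero_graph(baseline$graph_prot)
    baseline$graph_deprot <- zero_graph(baseline$graph_deprot)
  }
  if (!identical(dim(pair$graph_prot$x), dim(baseline$graph_prot$x)) ||
      !identical(dim(pair$graph_deprot$x), dim(baseline$graph_deprot$x)))
    stop("baseline shapes do not match the input pair")
  Bx <- pair_batches(list(pair))
  Bb <- pair_batches(list(baseline))
  dx <- list(xp = Bx$Bp$x - Bb$Bp$x, xd = Bx$Bd$x - Bb$Bd$x,
             ep = Bx$Bp$edge_attr - Bb$Bp$edge_attr,
             ed = Bx$Bd$edge_attr - Bb$Bd$edge_attr,
             mp = Bx$Bp$mol_features - Bb$Bp$mol_features,
             md = Bx$Bd$mol_features - Bb$Bd$mol_features)
  acc <- lapply(dx, function(m) m * 0)
  for (s in seq_len(steps)) {
    a <- (s - 0.5) / steps
    Bi <- Bx
    Bi$Bp$x <- Bb$Bp$x + a * dx$xp
    Bi$Bd$x <- Bb$Bd$x + a * dx$xd
    Bi$Bp$edge_attr <- Bb$Bp$edge_attr + a * dx$ep
    Bi$Bd$edge_attr <- Bb$Bd$edge_attr + a * dx$ed
    Bi$Bp$mol_features <- Bb$Bp$mol_features + a * dx$mp
    Bi$Bd$mol_features <- Bb$Bd$mol_features + a * dx$md
    gr <- nn_pair_pass(model$params, Bi$Bp, Bi$Bd, model$config,
                       want_input_grad = TRUE)$input_grads
    acc$xp <- acc$xp + gr$x_prot
    acc$xd <- acc$xd + gr$x_deprot
    acc$ep <- acc$ep + gr$e_prot
    acc$ed <- acc$ed + gr$e_deprot
    acc$mp <- acc$mp + gr$mol_prot
    acc$md <- acc$md + gr$mol_deprot
  }
  ys <- model$y_scale %||% 1
  yc <- model$y_center %||% 0
  attr_list <- mapply(function(a, d) ys * a / steps * d, acc, dx,
                      SIMPLIFY = FALSE)
  f_in <- yc + ys * nn_pair_pass(model$params, Bx$Bp, Bx$Bd,
                                 model$config)$pred
  f_base <- yc + ys * nn_pair_pass(model$params, Bb$Bp, Bb$Bd,
                                   model$config)$pred
  list(x_prot = attr_list$xp, x_deprot = attr_list$xd,
       e_prot = attr_list$ep, e_deprot = attr_list$ed,
       mol_prot = attr_list$mp, mol_deprot = attr_list$md,
       f_input = f_in, f_baseline = f_base,
       total = sum(vapply(attr_list, sum, 0)))
}

#' Aggregate integrated-gradients attributions by feature block
#'
#' @param ig Result of [integrated_gradients()].
#' @param schema Feature schema.
#' @return data.frame `feature`, `kind` (node/edge/mol), `attribution`
#'   (summed over atoms/arcs and both branches), sorted by |attribution|.
#' @export
ig_by_feature <- function(ig, schema = feature_schema()) {
  node_names <- schema_feature_names(schema, "node")
  edge_names <- schema_feature_names(schema, "edge")
  mol_names <- schema_feature_names(schema, "mol")
  node <- colSums(ig$x_prot) + colSums(ig$x_deprot)
  edge <- colSums(ig$e_prot) + colSums(ig$e_deprot)
  mol <- colSums(ig$mol_prot) + colSums(ig$mol_deprot)
  out <- rbind(
    data.frame(feature = node_names, kind = "node", attribution = node),
    data.frame(feature = edge_names, kind = "edge", attribution = edge),
    data.frame(feature = mol_names, kind = "mol", attribution = mol))
  out[order(-abs(out$attribution)), ]
}

# --- model serialization ---------------------------------------------------

#' Save a model (site or pKa) as JSON
#'
#' Weights, configuration, schema hash, stage/reaction and seeds are stored
#' in one JSON file (text, full precision) so trained artifacts survive in
#' text-only repositories and inference can verify the schema hash.
#'
#' @param model `site_model` or `pka_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$.class <- class(model)
  obj$history <- NULL  # keep artifacts small; history lives in provenance
  # matrices encoded explicitly (dims + column-major data) so the reader
  # never has to guess shapes
  enc <- function(p) {
    if (is.matrix(p)) return(list(.mat = dim(p), data = as.numeric(p)))
    if (is.list(p)) return(lapply(p, enc))
    p
  }
  obj$params <- enc(obj$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path JSON path.
#' @return The model object with its original class.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cls <- obj$.class
  obj$.class <- NULL
  dec <- function(p) {
    if (is.list(p) && !is.null(p$.mat))
      return(matrix(p$data, p$.mat[1], p$.mat[2]))
    if (is.list(p)) return(lapply(p, dec))
    p
  }
  obj$params <- dec(obj$params)
  structure(obj, class = cls)
}
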