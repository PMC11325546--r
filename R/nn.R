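# Graph neural network engine. Implements three message-passing families --
# "gcn" (degree-normalized convolution), "gat" (additive attention) and
# "gtr" (dot-product/transformer attention) -- with edge-feature
# projections, global mean pooling, and a linear head, entirely in base R
# matrix algebra with hand-derived reverse-mode gradients and an Adam
# optimizer. Molecule batches are merged into one block-diagonal graph so
# each training step is a handful of BLAS calls.
#
# Gradients are verified against central finite differences in the test
# suite; integrated-gradients attribution reuses the same backward pass to
# obtain input-feature gradients.

# --- batching --------------------------------------------------------------

#' Merge a list of graphs into one block-diagonal batch
#'
#' Adds self-loop arcs (with zero edge features) and precomputes the
#' symmetric GCN normalization 1/sqrt(d_u d_v).
#'
#' @param graphs List of `mol_graph`s.
#' @return Batch list used by the network forward/backward passes.
#' @keywords internal
batch_graphs <- function(graphs) {
  nf <- ncol(graphs[[1]]$x)
  ne <- ncol(graphs[[1]]$edge_attr)
  ns <- vapply(graphs, function(g) as.integer(g$n_atoms), 0L)
  offs <- cumsum(c(0L, ns[-length(ns)]))
  N <- sum(ns)
  x <- do.call(rbind, lapply(graphs, `[[`, "x"))
  us <- integer(); vs <- integer()
  eas <- vector("list", length(graphs))
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    if (ncol(g$edge_index) > 0L) {
      us <- c(us, g$edge_index[1, ] + offs[k])
      vs <- c(vs, g$edge_index[2, ] + offs[k])
      eas[[k]] <- g$edge_attr
    }
  }
  ea <- if (length(us)) do.call(rbind, eas) else
    matrix(0, 0, ne)
  # self loops
  us <- c(us, seq_len(N)); vs <- c(vs, seq_len(N))
  ea <- rbind(ea, matrix(0, N, ne))
  deg <- tabulate(vs, nbins = N)
  cgcn <- 1 / sqrt(deg[us] * deg[vs])
  gid <- rep(seq_along(graphs), ns)
  molf <- do.call(rbind, lapply(graphs, function(g)
    as.numeric(g$mol_features)))
  list(x = x, u = us, v = vs, edge_attr = ea, cgcn = cgcn,
       graph_id = gid, n_nodes = N, n_graphs = length(graphs),
       n_per_graph = ns, mol_features = molf,
       vf = factor(vs, levels = seq_len(N)),
       uf = factor(us, levels = seq_len(N)))
}

rs <- function(m, f) {
  out <- rowsum(m, f)
  rownames(out) <- NULL
  out
}

seg_softmax <- function(e, vf) {
  ee <- exp(e - max(e))
  denom <- rs(matrix(ee, ncol = 1), vf)[as.integer(vf), 1]
  ee / denom
}

lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
dlrelu <- function(x) ifelse(x > 0, 1, 0.2)

# --- parameters ------------------------------------------------------------

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# One message-passing layer's parameters.
init_layer <- function(din, dout, ne, family) {
  p <- list(W = glorot(din, dout), We = glorot(ne, dout) * 0.1,
            b = matrix(0, 1, dout))
  if (family == "gat") {
    p$a_src <- matrix(stats::rnorm(dout, 0, 0.1), dout, 1)
    p$a_dst <- matrix(stats::rnorm(dout, 0, 0.1), dout, 1)
    p$a_e <- matrix(stats::rnorm(ne, 0, 0.1), ne, 1)
  } else if (family == "gtr") {
    p$Wq <- glorot(din, dout)
    p$Wk <- glorot(din, dout)
  }
  p
}

#' Initialize network parameters
#' @keywords internal
nn_init <- function(config, seed) {
  with_seed(seed, {
    nf <- config$n_node_features
    ne <- config$n_edge_features
    h <- config$hidden
    enc <- vector("list", config$n_layers)
    din <- nf
    for (l in seq_len(config$n_layers)) {
      enc[[l]] <- init_layer(din, h, ne, config$family)
      din <- h
    }
    head <- list()
    if (config$task == "node") {
      head$W1 <- glorot(h, 1)
      head$b1 <- matrix(0, 1, 1)
    } else {
      din <- 2 * h + 2 * config$n_mol_features
      hw <- config$head_hidden
      for (k in seq_along(hw)) {
        head[[paste0("W", k)]] <- glorot(din, hw[k])
        head[[paste0("b", k)]] <- matrix(0, 1, hw[k])
        din <- hw[k]
      }
      head$Wout <- glorot(din, 1)
      head$bout <- matrix(0, 1, 1)
    }
    list(enc = enc, head = head)
  })
}

# --- encoder forward / backward -------------------------------------------

layer_forward <- function(p, X, B, family) {
  P <- X %*% p$W
  Em <- B$edge_attr %*% p$We
  if (family == "gcn") {
    msg <- (P[B$u, , drop = FALSE] + Em) * B$cgcn
    alpha <- NULL; cache_extra <- NULL
  } else if (family == "gat") {
    s <- P %*% p$a_src
    t <- P %*% p$a_dst
    epre <- s[B$u, 1] + t[B$v, 1] + (B$edge_attr %*% p$a_e)[, 1]
    e <- lrelu(epre)
    alpha <- seg_softmax(e, B$vf)
    msg <- (P[B$u, , drop = FALSE] + Em) * alpha
    cache_extra <- list(epre = epre)
  } else {  # gtr
    Q <- X %*% p$Wq
    K <- X %*% p$Wk
    e <- rowSums(Q[B$v, , drop = FALSE] * K[B$u, , drop = FALSE]) /
      sqrt(ncol(P))
    alpha <- seg_softmax(e, B$vf)
    msg <- (P[B$u, , drop = FALSE] + Em) * alpha
    cache_extra <- list(Q = Q, K = K)
  }
  Z <- rs(msg, B$vf) + matrix(p$b, nrow(P), ncol(P), byrow = TRUE)
  H <- pmax(Z, 0)
  list(H = H, cache = list(X = X, P = P, Em = Em, Z = Z, alpha = alpha,
                           extra = cache_extra))
}

layer_backward <- function(p, cache, dH, B, family) {
  dZ <- dH * (cache$Z > 0)
  db <- matrix(colSums(dZ), 1)
  dmsg <- dZ[B$v, , drop = FALSE]
  Pu <- cache$P[B$u, , drop = FALSE]
  g <- list(b = db)
  dEA <- NULL  # gradient w.r.t. input edge features (for attribution)
  if (family == "gcn") {
    dme <- dmsg * B$cgcn
    dP <- rs(dme, B$uf)
    dEm <- dme
    dX <- dP %*% t(p$W)
    dEA <- dEm %*% t(p$We)
    g$W <- crossprod(cache$X, dP)
    g$We <- crossprod(B$edge_attr, dEm)
  } else {
    alpha <- cache$alpha
    core <- Pu + cache$Em
    dalpha <- rowSums(dmsg * core)
    dcore <- dmsg * alpha
    seg <- rs(matrix(alpha * dalpha, ncol = 1), B$vf)[as.integer(B$vf), 1]
    de <- alpha * (dalpha - seg)
    dP <- rs(dcore, B$uf)
    dEm <- dcore
    if (family == "gat") {
      depre <- de * dlrelu(cache$extra$epre)
      ds <- rs(matrix(depre, ncol = 1), B$uf)
      dt <- rs(matrix(depre, ncol = 1), B$vf)
      dP <- dP + ds %*% t(p$a_src) + dt %*% t(p$a_dst)
      g$a_src <- crossprod(cache$P, ds)
      g$a_dst <- crossprod(cache$P, dt)
      g$a_e <- crossprod(B$edge_attr, matrix(depre, ncol = 1))
      dX <- dP %*% t(p$W)
      dEA <- dEm %*% t(p$We) + matrix(depre, ncol = 1) %*% t(p$a_e)
      g$W <- crossprod(cache$X, dP)
      g$We <- crossprod(B$edge_attr, dEm)
    } else {
      scale <- 1 / sqrt(ncol(cache$P))
      Q <- cache$extra$Q; K <- cache$extra$K
      dQ <- rs(de * K[B$u, , drop = FALSE] * scale, B$vf)
      dK <- rs(de * Q[B$v, , drop = FALSE] * scale, B$uf)
      dX <- dP %*% t(p$W) + dQ %*% t(p$Wq) + dK %*% t(p$Wk)
      dEA <- dEm %*% t(p$We)
      g$W <- crossprod(cache$X, dP)
      g$We <- crossprod(B$edge_attr, dEm)
      g$Wq <- crossprod(cache$X, dQ)
      g$Wk <- crossprod(cache$X, dK)
    }
  }
  list(dX = dX, dEA = dEA, grads = g)
}

encoder_forward <- function(params, B, config) {
  H <- B$x
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    fw <- layer_forward(params$enc[[l]], H, B, config$family)
    H <- fw$H
    caches[[l]] <- fw$cache
  }
  list(H = H, caches = caches)
}

encoder_backward <- function(params, caches, dH, B, config) {
  grads <- vector("list", config$n_layers)
  dEA <- 0
  for (l in rev(seq_len(config$n_layers))) {
    bw <- layer_backward(params$enc[[l]], caches[[l]], dH, B, config$family)
    grads[[l]] <- bw$grads
    dH <- bw$dX
    dEA <- dEA + bw$dEA
  }
  list(grads = grads, dX = dH, dEA = dEA)
}

# --- task heads ------------------------------------------------------------

# Node classification: per-node logit. Returns predictions, loss (weighted
# binary cross-entropy) and, if labels given and want_grad, all gradients.
nn_node_pass <- function(params, B, config, labels = NULL, pos_weight = 1,
                         want_grad = FALSE) {
  ef <- encoder_forward(params, B, config)
  z <- ef$H %*% params$head$W1 + params$head$b1[1, 1]
  prob <- 1 / (1 + exp(-z))
  out <- list(prob = as.numeric(prob), logits = as.numeric(z))
  if (!is.null(labels)) {
    y <- as.numeric(labels)
    w <- ifelse(y > 0.5, pos_weight, 1)
    # stable BCE: max(z,0) - z*y + log1p(exp(-|z|))
    out$loss <- sum(w * (pmax(z, 0) - z * y + log1p(exp(-abs(z))))) / sum(w)
    if (want_grad) {
      dz <- matrix(w * (prob - y) / sum(w), ncol = 1)
      gW1 <- crossprod(ef$H, dz)
      gb1 <- matrix(sum(dz), 1, 1)
      dH <- dz %*% t(params$head$W1)
      eb <- encoder_backward(params, ef$caches, dH, B, config)
      out$grads <- list(enc = eb$grads, head = list(W1 = gW1, b1 = gb1))
    }
  }
  out
}

# Mean pooling matrix application: pooled[g,] = mean over nodes of graph g.
pool_mean <- function(H, B) {
  rs(H / B$n_per_graph[B$graph_id], factor(B$graph_id,
                                           levels = seq_len(B$n_graphs)))
}

unpool_mean <- function(dpool, B) {
  dpool[B$graph_id, , drop = FALSE] / B$n_per_graph[B$graph_id]
}

# Paired-graph regression: shared encoder on the protonated and
# deprotonated batches, mean pooling, concatenation with both molecular
# feature vectors, MLP head, scalar output.
nn_pair_pass <- function(params, Bp, Bd, config, targets = NULL,
                         want_grad = FALSE, want_input_grad = FALSE) {
  efp <- encoder_forward(params, Bp, config)
  efd <- encoder_forward(params, Bd, config)
  poolp <- pool_mean(efp$H, Bp)
  poold <- pool_mean(efd$H, Bd)
  feat <- cbind(poolp, poold, Bp$mol_features, Bd$mol_features)
  hw <- config$head_hidden
  acts <- list(feat)
  A <- feat
  for (k in seq_along(hw)) {
    A <- pmax(A %*% params$head[[paste0("W", k)]] +
                matrix(params$head[[paste0("b", k)]], nrow(A),
                       hw[k], byrow = TRUE), 0)
    acts[[k + 1L]] <- A
  }
  yhat <- as.numeric(A %*% params$head$Wout + params$head$bout[1, 1])
  out <- list(pred = yhat)
  if (!is.null(targets) || want_input_grad) {
    nB <- length(yhat)
    if (!is.null(targets)) {
      err <- yhat - targets
      out$loss <- mean(err^2)
      dy <- matrix(2 * err / nB, ncol = 1)
    } else dy <- matrix(1, nB, 1)  # d(sum of outputs)/d inputs
    if (want_grad || want_input_grad) {
      gh <- list()
      dA <- dy %*% t(params$head$Wout)
      gh$Wout <- crossprod(acts[[length(acts)]], dy)
      gh$bout <- matrix(sum(dy), 1, 1)
      for (k in rev(seq_along(hw))) {
        dA <- dA * (acts[[k + 1L]] > 0)
        gh[[paste0("W", k)]] <- crossprod(acts[[k]], dA)
        gh[[paste0("b", k)]] <- matrix(colSums(dA), 1)
        dA <- dA %*% t(params$head[[paste0("W", k)]])
      }
      h <- config$hidden
      nm <- config$n_mol_features
      dpoolp <- dA[, seq_len(h), drop = FALSE]
      dpoold <- dA[, h + seq_len(h), drop = FALSE]
      dmolp <- dA[, 2 * h + seq_len(nm), drop = FALSE]
      dmold <- dA[, 2 * h + nm + seq_len(nm), drop = FALSE]
      ebp <- encoder_backward(params, efp$caches, unpool_mean(dpoolp, Bp),
                              Bp, config)
      ebd <- encoder_backward(params, efd$caches, unpool_mean(dpoold, Bd),
                              Bd, config)
      if (want_grad) {
        enc_g <- mapply(function(g1, g2) mapply(function(a, b) a + b, g1, g2,
                                                SIMPLIFY = FALSE),
                        ebp$grads, ebd$grads, SIMPLIFY = FALSE)
        out$grads <- list(enc = enc_g, head = gh)
      }
      if (want_input_grad)
        out$input_grads <- list(x_prot = ebp$dX, x_deprot = ebd$dX,
                                e_prot = ebp$dEA, e_deprot = ebd$dEA,
                                mol_prot = dmolp, mol_deprot = dmold)
    }
  }
  out
}

# --- optimizer -------------------------------------------------------------

# Flatten nested parameter/gradient lists for elementwise Adam updates.
flat_apply <- function(params, grads, fun) {
  if (is.matrix(params)) return(fun(params, grads))
  out <- params
  for (nm in names(params)) {
    if (is.null(grads[[nm]])) next
    out[[nm]] <- flat_apply(params[[nm]], grads[[nm]], fun)
  }
  for (k in seq_along(params)) {
    if (!is.null(names(params)) && nzchar(names(params)[k] %||% "")) next
    if (k > length(grads) || is.null(grads[[k]])) next
    out[[k]] <- flat_apply(params[[k]], grads[[k]], fun)
  }
  out
}

adam_new <- function(params) {
  zero <- function(p, g) p * 0
  list(m = flat_apply(params, params, zero),
       v = flat_apply(params, params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- flat_apply(state$m, grads, function(m, g) beta1 * m +
                          (1 - beta1) * g)
  state$v <- flat_apply(state$v, grads, function(v, g) beta2 * v +
                          (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- flat_apply(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- flat_apply(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# --- training loop ---------------------------------------------------------

# Generic seeded minibatch loop with early stopping on validation loss.
# Minibatches are materialized once (seeded partition of the training set)
# and revisited in a reshuffled order each epoch -- graph batch assembly is
# far more expensive in R than the matrix algebra itself.
# step_fn(params, batch) -> list(loss, grads); val_fn(params) -> scalar.
train_loop <- function(params, batches, step_fn, val_fn, config) {
  state <- adam_new(params)
  best <- list(params = params, val = Inf, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  patience <- config$patience
  wait <- 0L
  nb <- length(batches)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(config$seed * 10000 + epoch, sample.int(nb))
    tl <- 0
    for (bi in ord) {
      st <- step_fn(params, batches[[bi]])
      upd <- adam_step(params, st$grads, state, config$lr)
      params <- upd$params; state <- upd$state
      tl <- tl + st$loss
    }
    vl <- val_fn(params)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl / nb,
                                         val_loss = vl))
    if (vl < best$val - 1e-6) {
      best <- list(params = params, val = vl, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(params = best$params, best_val = best$val, best_epoch = best$epoch,
       history = history)
}

# Seeded partition of indices into minibatches of size <= bs.
make_minibatch_indices <- function(idx, bs, seed) {
  ord <- with_seed(seed, sample(idx))
  split(ord, ceiling(seq_along(ord) / bs))
}

# 80:10:10 (or custom) split *by molecule id*, seeded.
split_by_molecule <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 0) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  uids <- unique(ids)
  ord <- with_seed(seed, sample(uids))
  nu <- length(uids)
  n1 <- floor(fractions[1] * nu)
  n2 <- floor((fractions[1] + fractions[2]) * nu)
  g1 <- ord[seq_len(n1)]
  g2 <- if (n2 > n1) ord[(n1 + 1L):n2] else character(0)
  g3 <- if (nu > n2) ord[(n2 + 1L):nu] else character(0)
  list(train = which(ids %in% g1), val = which(ids %in% g2),
       test = which(ids %in% g3))
}
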