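# Model-facing graph representation. Every molecule becomes a graph with a
# locked 61-dimensional node-feature schema (topological one-hots plus the
# semiempirical per-atom quantities), 7 edge features per directed arc, and
# a 6-slot molecular feature vector (five 3D shape/graph descriptors plus
# the protonation energy, populated only for pairs). The schema is hashed
# and stored with trained models so inference can refuse mismatched inputs.

COVALENT_RADIUS <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                     I = 1.39)

#' The locked feature schema
#'
#' Node blocks sum to exactly 61 features; a unit test locks the total so
#' schema edits are deliberate. Named semiempirical features each occupy
#' one slot ("xTB Partial Charge", "xTB Fukui(+/0/-)", "xTB Coord Number",
#' "xTB Alpha"); edges carry a bond-type one-hot ("Bond Type: SINGLE" first),
#' conjugation, ring membership and the Wiberg bond order; molecular slots
#' are RadiusOfGyration, Eccentricity, Spherocity, FractionCSP3, Asphericity
#' and xTB-Energy.
#'
#' @return Object of class `feature_schema` with `node_blocks`,
#'   `edge_blocks`, `mol_blocks` (named width vectors) and `hash`.
#' @export
feature_schema <- function() {
  node_blocks <- c(
    "atom_type" = 11L,       # C,N,O,S,P,F,Cl,Br,I,H,other
    "formal_charge" = 5L,    # -2..+2 one-hot (clamped)
    "degree" = 6L,           # 0..5 explicit connections (clamped)
    "total_h" = 5L,          # 0..4 bonded hydrogens (clamped)
    "hybridization" = 4L,    # sp, sp2, sp3, other
    "aromatic" = 1L,
    "in_ring" = 1L,
    "is_hbd" = 1L,
    "is_hba" = 1L,
    "xtb_partial_charge" = 1L,
    "xtb_fukui_plus" = 1L,
    "xtb_fukui_zero" = 1L,
    "xtb_fukui_minus" = 1L,
    "xtb_coord_number" = 1L,
    "xtb_alpha" = 1L,
    "lone_pairs" = 1L,
    "heavy_degree" = 1L,
    "valence" = 7L,          # 0..6 rounded bond-order sum (clamped)
    "electronegativity" = 1L,
    "covalent_radius" = 1L,
    "atomic_mass" = 1L,
    "heteroatom" = 1L,
    "terminal" = 1L,
    "ring_size" = 6L)        # none,3,4,5,6,7+
  edge_blocks <- c("bond_type" = 4L,  # SINGLE, AROMATIC, DOUBLE, TRIPLE
                   "conjugated" = 1L, "in_ring" = 1L, "wiberg" = 1L)
  mol_blocks <- c("RadiusOfGyration" = 1L, "Eccentricity" = 1L,
                  "Spherocity" = 1L, "FractionCSP3" = 1L,
                  "Asphericity" = 1L, "xTB-Energy" = 1L)
  sch <- list(node_blocks = node_blocks, edge_blocks = edge_blocks,
              mol_blocks = mol_blocks, n_node_features = sum(node_blocks),
              n_edge_features = sum(edge_blocks),
              n_mol_features = sum(mol_blocks))
  sch$hash <- stable_hash(paste(c(names(node_blocks), node_blocks,
                                  names(edge_blocks), edge_blocks,
                                  names(mol_blocks), mol_blocks),
                                collapse = "|"))
  class(sch) <- "feature_schema"
  sch
}

onehot <- function(value, levels) as.numeric(levels == value)

# sp / sp2 / sp3 / other from bond orders around the atom
.hybridization <- function(element, aromatic, orders) {
  if (!element %in% c("C", "N", "O", "S", "P")) return("other")
  if (any(orders == 3) || sum(orders == 2) >= 2) return("sp")
  if (aromatic || any(orders == 2)) return("sp2")
  "sp3"
}

#' 3D shape and hybridization descriptors
#'
#' Computes the five molecular descriptor slots from the conformer:
#' mass-weighted gyration tensor S = sum_i m_i (r_i - rbar)(r_i - rbar)^T /
#' sum_i m_i with eigenvalues l1 >= l2 >= l3, then
#'   RadiusOfGyration = sqrt(l1 + l2 + l3)
#'   Asphericity      = ((l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2) / (2 (l1+l2+l3)^2)
#'   Eccentricity     = sqrt(1 - l3^2 / l1^2)
#'   Spherocity       = 3 l3 / (l1 + l2 + l3)
#' plus FractionCSP3 = (sp3 carbons) / (carbons). Degenerate inputs (< 3
#' atoms, or all coordinates coincident) yield 0 for all shape descriptors
#' rather than NaN.
#'
#' @param mol `mol_record` with conformer.
#' @return Named numeric vector of the five descriptors.
#' @export
molecular_descriptors <- function(mol) {
  el <- mol$atoms$element
  ncarbon <- sum(el == "C")
  sp3 <- 0L
  bm <- mol_bond_matrix(mol)
  for (i in which(el == "C")) {
    orders <- bm[i, bm[i, ] > 0]
    if (.hybridization("C", mol$atoms$aromatic[i], orders) == "sp3")
      sp3 <- sp3 + 1L
  }
  fcsp3 <- if (ncarbon > 0L) sp3 / ncarbon else 0
  out <- c(RadiusOfGyration = 0, Eccentricity = 0, Spherocity = 0,
           FractionCSP3 = fcsp3, Asphericity = 0)
  xyz <- mol$coords
  if (is.null(xyz) || nrow(xyz) < 3L) return(out)
  mass <- ifelse(el %in% names(ATOMIC_MASS), ATOMIC_MASS[el], 12)
  ctr <- colSums(xyz * mass) / sum(mass)
  d <- sweep(xyz, 2, ctr)
  S <- crossprod(d * mass, d) / sum(mass)
  ev <- sort(pmax(0, eigen(S, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  tr <- sum(ev)
  if (tr < 1e-12) return(out)
  out["RadiusOfGyration"] <- sqrt(tr)
  out["Asphericity"] <- ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                           (ev[1] - ev[3])^2) / (2 * tr^2)
  out["Eccentricity"] <- sqrt(max(0, 1 - ev[3]^2 / ev[1]^2))
  out["Spherocity"] <- 3 * ev[3] / tr
  out
}

#' Build the model-facing graph for one molecule
#'
#' @param mol Standardized `mol_record` (explicit hydrogens, conformer).
#' @param qm Matching `mol_qm` from [compute_qm()].
#' @param schema A `feature_schema` (default: the package schema).
#' @return Object of class `mol_graph`: `x` (N x 61 node-feature matrix),
#'   `edge_index` (2 x 2E, each bond as two directed arcs, 1-based),
#'   `edge_attr` (2E x 7), `mol_features` (length 6), `n_atoms`,
#'   `schema_hash`, `id`, `smiles`.
#' @export
featurize <- function(mol, qm, schema = feature_schema()) {
  n <- n_atoms(mol)
  if (length(qm$partial_charge) != n)
    stop("qm features are misaligned with the molecule (atom count)")
  if (length(qm$wiberg_order) != nrow(mol$bonds))
    stop("qm features are misaligned with the molecule (bond count)")
  el <- mol$atoms$element
  nb <- mol_neighbors(mol)
  bm <- mol_bond_matrix(mol)
  deg <- vapply(nb, length, 1L)
  totH <- vapply(seq_len(n), function(i)
    mol$atoms$nH[i] + sum(el[nb[[i]]] == "H"), 0)
  ringf <- ring_atom_flags(mol)
  rsize <- smallest_ring_sizes(mol)
  types <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "H")
  hyb_levels <- c("sp", "sp2", "sp3", "other")
  x <- matrix(0, n, schema$n_node_features)
  for (i in seq_len(n)) {
    orders <- bm[i, bm[i, ] > 0]
    hyb <- .hybridization(el[i], mol$atoms$aromatic[i], orders)
    lp <- .lone_pairs_now(el[i], mol$atoms$charge[i])
    row <- c(
      if (el[i] %in% types) onehot(el[i], types) else rep(0, 10), # atom_type
      if (el[i] %in% types) 0 else 1,                             # ..other
      onehot(max(-2L, min(2L, mol$atoms$charge[i])), -2:2),
      onehot(min(deg[i], 5L), 0:5),
      onehot(min(totH[i], 4L), 0:4),
      onehot(hyb, hyb_levels),
      as.numeric(mol$atoms$aromatic[i]),
      as.numeric(ringf[i]),
      as.numeric(el[i] %in% c("N", "O", "S") && totH[i] >= 1),    # is_hbd
      as.numeric(el[i] %in% c("N", "O") && lp > 0 &&
                   mol$atoms$charge[i] <= 0),                     # is_hba
      qm$partial_charge[i],
      qm$fukui_plus[i], qm$fukui_zero[i], qm$fukui_minus[i],
      qm$coord_number[i], qm$polarizability[i] / 10,
      lp,
      sum(el[nb[[i]]] != "H"),
      onehot(max(0L, min(6L, round(sum(orders) + mol$atoms$nH[i]))), 0:6),
      en_of(el[i]) / 4,
      unname(ifelse(el[i] %in% names(COVALENT_RADIUS),
                    COVALENT_RADIUS[el[i]], 1)),
      unname(ifelse(el[i] %in% names(ATOMIC_MASS),
                    ATOMIC_MASS[el[i]], 50)) / 100,
      as.numeric(!el[i] %in% c("C", "H")),
      as.numeric(deg[i] == 1L),
      onehot(if (rsize[i] == 0L) "none" else if (rsize[i] >= 7L) "7+" else
        as.character(rsize[i]), c("none", "3", "4", "5", "6", "7+")))
    x[i, ] <- row
  }
  colnames(x) <- schema_feature_names(schema, "node")
  nb_bonds <- nrow(mol$bonds)
  if (nb_bonds > 0L) {
    ei <- rbind(c(mol$bonds$i, mol$bonds$j), c(mol$bonds$j, mol$bonds$i))
    rb <- ring_bond_flags(mol)
    hybs <- vapply(seq_len(n), function(i)
      .hybridization(el[i], mol$atoms$aromatic[i], bm[i, bm[i, ] > 0]), "")
    conj <- (mol$atoms$aromatic[mol$bonds$i] | hybs[mol$bonds$i] == "sp2") &
      (mol$atoms$aromatic[mol$bonds$j] | hybs[mol$bonds$j] == "sp2")
    ea1 <- t(vapply(seq_len(nb_bonds), function(k) {
      o <- mol$bonds$order[k]
      c(onehot(o, c(1, 1.5, 2, 3)), as.numeric(conj[k]), as.numeric(rb[k]),
        qm$wiberg_order[k])
    }, numeric(7)))
    ea <- rbind(ea1, ea1)  # identical features on both arcs
  } else {
    ei <- matrix(integer(), 2, 0)
    ea <- matrix(numeric(), 0, schema$n_edge_features)
  }
  colnames(ea) <- schema_feature_names(schema, "edge")
  mf <- c(molecular_descriptors(mol), "xTB-Energy" = 0)
  if (any(!is.finite(x))) {
    bad <- which(colSums(!is.finite(x)) > 0)[1]
    stop("non-finite node feature in block '", colnames(x)[bad], "'")
  }
  if (any(!is.finite(ea))) stop("non-finite edge feature (wiberg block?)")
  if (any(!is.finite(mf))) stop("non-finite molecular descriptor")
  structure(list(x = x, edge_index = ei, edge_attr = ea,
                 mol_features = mf, n_atoms = n,
                 schema_hash = schema$hash, id = mol$id,
                 smiles = mol$smiles),
            class = "mol_graph")
}

# Expanded per-slot feature names, e.g. "atom_type:C", "xtb_alpha".
schema_feature_names <- function(schema, which = c("node", "edge", "mol")) {
  which <- match.arg(which)
  blocks <- switch(which, node = schema$node_blocks,
                   edge = schema$edge_blocks, mol = schema$mol_blocks)
  lab <- list(
    atom_type = c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "H",
                  "other"),
    formal_charge = as.character(-2:2),
    degree = as.character(0:5), total_h = as.character(0:4),
    hybridization = c("sp", "sp2", "sp3", "other"),
    valence = as.character(0:6),
    ring_size = c("none", "3", "4", "5", "6", "7+"),
    bond_type = c("SINGLE", "AROMATIC", "DOUBLE", "TRIPLE"))
  unlist(lapply(names(blocks), function(bn) {
    w <- blocks[[bn]]
    if (w == 1L) bn else paste0(bn, ":", lab[[bn]])
  }), use.names = FALSE)
}

#' Featurize a protonated/deprotonated pair
#'
#' Verifies via [structural_change_filter()] that the two records differ by
#' exactly one proton, builds both graphs, and writes the protonation energy
#' E(protonated) - E(deprotonated) (Hartree) into the `xTB-Energy` molecular
#' feature slot of both graphs.
#'
#' @param protonated,deprotonated Lists `list(mol, qm)` for each form.
#' @param schema Feature schema.
#' @return List of two `mol_graph`s: `graph_prot`, `graph_deprot`.
#' @export
featurize_pair <- function(protonated, deprotonated,
                           schema = feature_schema()) {
  if (!structural_change_filter(deprotonated$mol, protonated$mol,
                                "protonation"))
    stop("pair rejected: forms do not differ by exactly one proton")
  de <- protonated$qm$total_energy - deprotonated$qm$total_energy
  gp <- featurize(protonated$mol, protonated$qm, schema)
  gd <- featurize(deprotonated$mol, deprotonated$qm, schema)
  gp$mol_features[["xTB-Energy"]] <- de
  gd$mol_features[["xTB-Energy"]] <- de
  list(graph_prot = gp, graph_deprot = gd)
}
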