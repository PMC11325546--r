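# Molecular graph core. A `mol_record` is a plain-R molecular graph: an atom
# table, a bond table (orders 1 / 1.5 / 2 / 3, aromatic bonds stored as 1.5),
# optional tetrahedral stereo, and one 3D conformer. Canonicalization and
# validation of SMILES strings are delegated to OpenBabel (ChemmineOB); all
# graph surgery (protonation edits, tautomer transforms, hydrogen handling)
# happens on this structure.

ORGANIC_ELEMENTS <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

# Standard valences used for implicit-hydrogen assignment of bare
# (organic-subset) SMILES atoms. Multi-valued entries: smallest valence that
# accommodates the explicit bonds is used (S 2/4/6, P 3/5).
.VALENCES <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
                  F = 1, Cl = 1, Br = 1, I = 1)

#' Construct a molecular record
#'
#' @param atoms data.frame with columns `element` (symbol), `charge`
#'   (integer, e), `nH` (implicit hydrogen count), `aromatic` (logical),
#'   `chiral` (0 none, 1 anticlockwise `@`, 2 clockwise `@@`).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 1.5, 2, 3).
#' @param id Molecule identifier.
#' @param chiral_nbrs Optional list (one entry per atom) giving, for chiral
#'   atoms, neighbour indices in stereo-reference order (0 = implicit H).
#' @param coords Optional N x 3 conformer matrix (Angstrom).
#' @param smiles Canonical SMILES if already known.
#' @return Object of class `mol_record`.
#' @keywords internal
mol_new <- function(atoms, bonds, id = NA_character_, chiral_nbrs = NULL,
                    coords = NULL, smiles = NA_character_, flagged = FALSE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds) == 0L)
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  stopifnot(all(c("element", "charge", "nH", "aromatic", "chiral") %in%
                  names(atoms)))
  if (nrow(bonds) > 0L) {
    stopifnot(all(bonds$i >= 1), all(bonds$j >= 1),
              all(bonds$i <= nrow(atoms)), all(bonds$j <= nrow(atoms)),
              all(bonds$order %in% c(1, 1.5, 2, 3)))
  }
  if (is.null(chiral_nbrs)) chiral_nbrs <- vector("list", nrow(atoms))
  structure(list(id = id, atoms = atoms, bonds = bonds,
                 chiral_nbrs = chiral_nbrs, coords = coords,
                 smiles = smiles, flagged = flagged),
            class = "mol_record")
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record %s: %d atoms (%d H implicit), %d bonds, charge %+d>\n",
              if (is.na(x$id)) "?" else x$id, nrow(x$atoms),
              sum(x$atoms$nH), nrow(x$bonds), mol_net_charge(x)))
  if (!is.na(x$smiles)) cat("  ", x$smiles, "\n", sep = "")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

#' Net formal charge of a molecule
#' @param mol A `mol_record`.
#' @return Integer net charge (e).
#' @export
mol_net_charge <- function(mol) as.integer(sum(mol$atoms$charge))

# Neighbour list: integer vector of bonded atoms per atom, ascending.
mol_neighbors <- function(mol) {
  nb <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) sort(unique(v)))
}

# Bond order lookup matrix (dense; molecules are small).
mol_bond_matrix <- function(mol) {
  n <- n_atoms(mol)
  bm <- matrix(0, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    bm[mol$bonds$i[k], mol$bonds$j[k]] <- mol$bonds$order[k]
    bm[mol$bonds$j[k], mol$bonds$i[k]] <- mol$bonds$order[k]
  }
  bm
}

# Implicit hydrogen count for a bare (organic subset, uncharged) atom given
# its bonds. Aromatic atoms: default_valence - connections - 1 (the -1
# accounts for the delocalized ring bond); aliphatic: smallest standard
# valence >= bond-order sum, minus that sum.
implicit_h_for <- function(element, aromatic, orders) {
  vals <- .VALENCES[[element]]
  if (is.null(vals)) return(0L)
  if (aromatic) return(max(0L, as.integer(vals[1] - length(orders) - 1L)))
  bs <- ceiling(sum(orders))
  v <- vals[vals >= bs]
  if (length(v) == 0L) return(0L)
  as.integer(v[1] - bs)
}

# Recompute what the implicit H count of atom idx would be if written bare.
mol_default_nH <- function(mol, idx) {
  sel <- mol$bonds$i == idx | mol$bonds$j == idx
  implicit_h_for(mol$atoms$element[idx], mol$atoms$aromatic[idx],
                 mol$bonds$order[sel])
}

#' Total hydrogen count of an atom (implicit + explicit neighbours)
#' @keywords internal
atom_total_h <- function(mol, idx, nb = NULL) {
  if (is.null(nb)) nb <- mol_neighbors(mol)
  mol$atoms$nH[idx] + sum(mol$atoms$element[nb[[idx]]] == "H")
}

# Molecular formula as a named count vector (H = implicit + explicit).
mol_formula <- function(mol) {
  el <- mol$atoms$element
  tab <- table(el[el != "H"])
  h <- sum(mol$atoms$nH) + sum(el == "H")
  out <- c(as.list(tab), list(H = h))
  out <- unlist(out)
  out <- out[out > 0]
  out[order(names(out))]
}

# Connected components (on the bond graph). Returns integer component id
# per atom.
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- rep(NA_integer_, n)
  nb <- mol_neighbors(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in nb[[a]]) if (is.na(comp[b])) { comp[b] <- cid; queue <- c(queue, b) }
    }
  }
  comp
}

# Keep a subset of atoms; bonds, stereo bookkeeping and coordinates are
# remapped. Atoms referenced by kept chiral lists but dropped (e.g. a removed
# explicit H) must be handled by the caller beforehand.
mol_subset <- function(mol, keep) {
  keep <- sort(keep)
  remap <- rep(NA_integer_, n_atoms(mol))
  remap[keep] <- seq_along(keep)
  bonds <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, ,
                     drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  cn <- lapply(mol$chiral_nbrs[keep], function(v) {
    if (is.null(v)) return(NULL)
    out <- v
    nz <- v != 0L  # 0 marks the implicit-H slot and must stay 0
    out[nz] <- remap[v[nz]]
    if (anyNA(out)) NULL else as.integer(out)
  })
  mol_new(mol$atoms[keep, , drop = FALSE], bonds, id = mol$id,
          chiral_nbrs = cn,
          coords = if (is.null(mol$coords)) NULL else
            mol$coords[keep, , drop = FALSE],
          smiles = NA_character_, flagged = mol$flagged)
}

#' Add explicit hydrogen atoms
#'
#' Converts all implicit hydrogens into explicit H atom nodes (appended after
#' the heavy atoms in atom order). Stereo reference lists that contained the
#' implicit-H placeholder are updated to point at the new H node.
#'
#' @param mol A `mol_record`.
#' @return A `mol_record` with `nH == 0` everywhere.
#' @export
add_explicit_h <- function(mol) {
  nh <- mol$atoms$nH
  if (all(nh == 0L)) return(mol)
  n0 <- n_atoms(mol)
  extra <- sum(nh)
  hat <- data.frame(element = rep("H", extra), charge = 0L, nH = 0L,
                    aromatic = FALSE, chiral = 0L, stringsAsFactors = FALSE)
  atoms <- rbind(mol$atoms, hat)
  atoms$nH <- 0L
  bonds <- mol$bonds
  cn <- c(mol$chiral_nbrs, vector("list", extra))
  nxt <- n0
  newb <- vector("list", extra)
  bi <- 0L
  for (a in seq_len(n0)) {
    if (nh[a] == 0L) next
    for (k in seq_len(nh[a])) {
      nxt <- nxt + 1L; bi <- bi + 1L
      newb[[bi]] <- data.frame(i = a, j = nxt, order = 1)
      if (k == 1L && !is.null(cn[[a]]))
        cn[[a]][cn[[a]] == 0L] <- nxt
    }
  }
  bonds <- rbind(bonds, do.call(rbind, newb))
  coords <- NULL  # conformer must be re-embedded after topology change
  mol_new(atoms, bonds, id = mol$id, chiral_nbrs = cn, coords = coords,
          smiles = mol$smiles, flagged = mol$flagged)
}

#' Strip explicit hydrogens back to implicit counts
#' @param mol A `mol_record`.
#' @return A `mol_record` whose terminal H atoms are folded into `nH`.
#' @export
strip_explicit_h <- function(mol) {
  nb <- mol_neighbors(mol)
  el <- mol$atoms$element
  drop <- which(el == "H" & vapply(nb, length, 1L) == 1L &
                  vapply(seq_along(nb), function(i)
                    length(nb[[i]]) == 1L && el[nb[[i]][1]] != "H", TRUE) &
                  mol$atoms$charge == 0L)
  if (length(drop) == 0L) return(mol)
  atoms <- mol$atoms
  cn <- mol$chiral_nbrs
  for (h in drop) {
    heavy <- nb[[h]][1]
    atoms$nH[heavy] <- atoms$nH[heavy] + 1L
    if (!is.null(cn[[heavy]])) cn[[heavy]][cn[[heavy]] == h] <- 0L
  }
  m2 <- mol_new(atoms, mol$bonds, id = mol$id, chiral_nbrs = cn,
                coords = mol$coords, smiles = mol$smiles,
                flagged = mol$flagged)
  mol_subset(m2, setdiff(seq_len(n_atoms(m2)), drop))
}

# --- ring perception -------------------------------------------------------

# Logical vector per bond: TRUE if the bond lies in a ring (i.e. is not a
# bridge). Iterative Tarjan bridge-finding.
ring_bond_flags <- function(mol) {
  n <- n_atoms(mol)
  nbonds <- nrow(mol$bonds)
  if (nbonds == 0L) return(logical(0))
  adj <- vector("list", n)  # list of (neighbor, bond index)
  for (k in seq_len(nbonds)) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], list(c(j, k)))
    adj[[j]] <- c(adj[[j]], list(c(i, k)))
  }
  disc <- rep(0L, n); low <- rep(0L, n)
  bridge <- rep(FALSE, nbonds)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    # iterative DFS with explicit stack: (node, incoming bond, next child ptr)
    stack <- list(list(v = root, pb = 0L, ci = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$ci <= length(adj[[v]])) {
        ent <- adj[[v]][[fr$ci]]
        stack[[length(stack)]]$ci <- fr$ci + 1L
        w <- ent[1]; bk <- ent[2]
        if (bk == fr$pb) next
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, pb = bk, ci = 1L)
        } else low[v] <- min(low[v], disc[w])
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          u <- stack[[length(stack)]]$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) bridge[fr$pb] <- TRUE
        }
      }
    }
  }
  !bridge
}

ring_atom_flags <- function(mol) {
  rb <- ring_bond_flags(mol)
  fl <- rep(FALSE, n_atoms(mol))
  if (any(rb)) {
    fl[mol$bonds$i[rb]] <- TRUE
    fl[mol$bonds$j[rb]] <- TRUE
  }
  fl
}

# Size of the smallest ring through each atom (0 for acyclic atoms).
smallest_ring_sizes <- function(mol) {
  rb <- ring_bond_flags(mol)
  n <- n_atoms(mol)
  out <- rep(0L, n)
  if (!any(rb)) return(out)
  nb <- mol_neighbors(mol)
  ring_atoms <- unique(c(mol$bonds$i[rb], mol$bonds$j[rb]))
  for (a in ring_atoms) {
    best <- Inf
    inc <- which(rb & (mol$bonds$i == a | mol$bonds$j == a))
    for (k in inc) {
      b <- if (mol$bonds$i[k] == a) mol$bonds$j[k] else mol$bonds$i[k]
      # BFS shortest path a..b avoiding bond k
      dist <- rep(NA_integer_, n); dist[a] <- 0L; queue <- a
      while (length(queue) && is.na(dist[b])) {
        v <- queue[1]; queue <- queue[-1]
        for (w in nb[[v]]) {
          if ((v == a && w == b) || (v == b && w == a)) {
            samebond <- (min(v, w) == min(a, b) && max(v, w) == max(a, b))
            if (samebond) next
          }
          if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
        }
      }
      if (!is.na(dist[b])) best <- min(best, dist[b] + 1L)
    }
    out[a] <- if (is.finite(best)) as.integer(best) else 0L
  }
  out
}

# All-pairs graph distances by BFS (small molecules; used for conformer
# embedding). Disconnected pairs get (diameter + 2).
graph_distances <- function(mol) {
  n <- n_atoms(mol)
  nb <- mol_neighbors(mol)
  D <- matrix(NA_real_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, n); dist[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1; queue <- c(queue, w)
      }
    }
    D[s, ] <- dist
  }
  mx <- max(D, na.rm = TRUE)
  D[is.na(D)] <- mx + 2
  D
}
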