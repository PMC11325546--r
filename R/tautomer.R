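# Tautomer enumeration and most-stable-tautomer selection. Enumeration uses
# a documented rule set of proton-shift transforms (keto/enol, amide/imidic
# acid, aromatic lactam/lactim); rule sets differ between toolkits, so the
# exact transforms applied here are spelled out below. The search is
# restricted to neutral molecules; the stable form is the argmin of the
# backend total energy in implicit water.

# Each transform returns a list of edited implicit-H `mol_record`s (possibly
# empty). `m` is a canonical-order implicit-H record.

.tautomer_rules <- list(
  # keto -> enol: H-C-C=O  =>  C=C-OH (all aliphatic)
  keto_to_enol = function(m) {
    out <- list()
    bm <- mol_bond_matrix(m)
    el <- m$atoms$element; ar <- m$atoms$aromatic
    for (k in seq_len(nrow(m$bonds))) {
      for (dir in 1:2) {
        b <- if (dir == 1) m$bonds$i[k] else m$bonds$j[k]  # carbonyl C
        cO <- if (dir == 1) m$bonds$j[k] else m$bonds$i[k]
        if (m$bonds$order[k] != 2 || el[b] != "C" || el[cO] != "O") next
        if (ar[b] || ar[cO]) next
        for (a in which(bm[b, ] == 1)) {
          if (el[a] != "C" || ar[a] || m$atoms$nH[a] < 1L) next
          e <- m
          e$atoms$nH[a] <- e$atoms$nH[a] - 1L
          e$atoms$nH[cO] <- e$atoms$nH[cO] + 1L
          e$bonds$order[e$bonds$i == min(a, b) & e$bonds$j == max(a, b) |
                          (e$bonds$i == max(a, b) & e$bonds$j == min(a, b))] <- 2
          e$bonds$order[k] <- 1
          out[[length(out) + 1L]] <- e
        }
      }
    }
    out
  },
  # enol -> keto: C=C-OH  =>  H-C-C=O
  enol_to_keto = function(m) {
    out <- list()
    bm <- mol_bond_matrix(m)
    el <- m$atoms$element; ar <- m$atoms$aromatic
    for (k in seq_len(nrow(m$bonds))) {
      if (m$bonds$order[k] != 2) next
      for (dir in 1:2) {
        a <- if (dir == 1) m$bonds$i[k] else m$bonds$j[k]
        b <- if (dir == 1) m$bonds$j[k] else m$bonds$i[k]
        if (el[a] != "C" || el[b] != "C" || ar[a] || ar[b]) next
        for (cO in which(bm[b, ] == 1)) {
          if (el[cO] != "O" || ar[cO] || m$atoms$nH[cO] < 1L ||
              m$atoms$charge[cO] != 0L) next
          e <- m
          e$atoms$nH[cO] <- e$atoms$nH[cO] - 1L
          e$atoms$nH[a] <- e$atoms$nH[a] + 1L
          e$bonds$order[k] <- 1
          e$bonds$order[(e$bonds$i == min(b, cO) & e$bonds$j == max(b, cO)) |
                          (e$bonds$i == max(b, cO) & e$bonds$j == min(b, cO))] <- 2
          out[[length(out) + 1L]] <- e
        }
      }
    }
    out
  },
  # amide -> imidic acid: HN-C=O => N=C-OH (aliphatic)
  amide_to_imidic = function(m) {
    out <- list()
    bm <- mol_bond_matrix(m)
    el <- m$atoms$element; ar <- m$atoms$aromatic
    for (k in seq_len(nrow(m$bonds))) {
      for (dir in 1:2) {
        b <- if (dir == 1) m$bonds$i[k] else m$bonds$j[k]
        cO <- if (dir == 1) m$bonds$j[k] else m$bonds$i[k]
        if (m$bonds$order[k] != 2 || el[b] != "C" || el[cO] != "O") next
        if (ar[b] || ar[cO]) next
        for (a in which(bm[b, ] == 1)) {
          if (el[a] != "N" || ar[a] || m$atoms$nH[a] < 1L ||
              m$atoms$charge[a] != 0L) next
          e <- m
          e$atoms$nH[a] <- e$atoms$nH[a] - 1L
          e$atoms$nH[cO] <- e$atoms$nH[cO] + 1L
          e$bonds$order[(e$bonds$i == min(a, b) & e$bonds$j == max(a, b)) |
                          (e$bonds$i == max(a, b) & e$bonds$j == min(a, b))] <- 2
          e$bonds$order[k] <- 1
          out[[length(out) + 1L]] <- e
        }
      }
    }
    out
  },
  # imidic acid -> amide: N=C-OH => HN-C=O
  imidic_to_amide = function(m) {
    out <- list()
    bm <- mol_bond_matrix(m)
    el <- m$atoms$element; ar <- m$atoms$aromatic
    for (k in seq_len(nrow(m$bonds))) {
      if (m$bonds$order[k] != 2) next
      for (dir in 1:2) {
        a <- if (dir == 1) m$bonds$i[k] else m$bonds$j[k]  # N
        b <- if (dir == 1) m$bonds$j[k] else m$bonds$i[k]  # C
        if (el[a] != "N" || el[b] != "C" || ar[a] || ar[b]) next
        for (cO in which(bm[b, ] == 1)) {
          if (el[cO] != "O" || ar[cO] || m$atoms$nH[cO] < 1L ||
              m$atoms$charge[cO] != 0L) next
          e <- m
          e$atoms$nH[cO] <- e$atoms$nH[cO] - 1L
          e$atoms$nH[a] <- e$atoms$nH[a] + 1L
          e$bonds$order[k] <- 1
          e$bonds$order[(e$bonds$i == min(b, cO) & e$bonds$j == max(b, cO)) |
                          (e$bonds$i == max(b, cO) & e$bonds$j == min(b, cO))] <- 2
          out[[length(out) + 1L]] <- e
        }
      }
    }
    out
  },
  # aromatic lactam -> lactim: [nH] adjacent to aromatic C with exocyclic =O
  lactam_to_lactim = function(m) {
    out <- list()
    bm <- mol_bond_matrix(m)
    el <- m$atoms$element; ar <- m$atoms$aromatic
    nHs <- which(el == "N" & ar & m$atoms$nH >= 1L & m$atoms$charge == 0L)
    for (a in nHs) {
      for (b in which(bm[a, ] == 1.5)) {
        if (el[b] != "C") next
        for (cO in which(bm[b, ] == 2)) {
          if (el[cO] != "O" || ar[cO]) next
          e <- m
          e$atoms$nH[a] <- e$atoms$nH[a] - 1L
          e$atoms$nH[cO] <- e$atoms$nH[cO] + 1L
          e$bonds$order[(e$bonds$i == min(b, cO) & e$bonds$j == max(b, cO)) |
                          (e$bonds$i == max(b, cO) & e$bonds$j == min(b, cO))] <- 1
          out[[length(out) + 1L]] <- e
        }
      }
    }
    out
  },
  # aromatic lactim -> lactam: pyridine-type n adjacent to aromatic C-OH
  lactim_to_lactam = function(m) {
    out <- list()
    bm <- mol_bond_matrix(m)
    el <- m$atoms$element; ar <- m$atoms$aromatic
    ns <- which(el == "N" & ar & m$atoms$nH == 0L & m$atoms$charge == 0L)
    for (a in ns) {
      for (b in which(bm[a, ] == 1.5)) {
        if (el[b] != "C") next
        for (cO in which(bm[b, ] == 1)) {
          if (el[cO] != "O" || ar[cO] || m$atoms$nH[cO] < 1L ||
              m$atoms$charge[cO] != 0L) next
          e <- m
          e$atoms$nH[cO] <- e$atoms$nH[cO] - 1L
          e$atoms$nH[a] <- e$atoms$nH[a] + 1L
          e$bonds$order[(e$bonds$i == min(b, cO) & e$bonds$j == max(b, cO)) |
                          (e$bonds$i == max(b, cO) & e$bonds$j == min(b, cO))] <- 2
          out[[length(out) + 1L]] <- e
        }
      }
    }
    out
  }
)

#' Enumerate neutral tautomers
#'
#' Breadth-first application of the package's proton-shift transform rules,
#' deduplicated by canonical SMILES. The input's canonical form is always
#' element 1 of the result. Every candidate is validated by OpenBabel
#' round-trip and must conserve molecular formula and zero net charge.
#'
#' @param mol Neutral `mol_record` (standardized or not).
#' @param max_tautomers Cap on the returned list (default 64); hitting the
#'   cap logs a warning.
#' @return List of implicit-hydrogen `mol_record`s in canonical atom order.
#' @export
enumerate_tautomers <- function(mol, max_tautomers = 64L) {
  if (mol_net_charge(mol) != 0L)
    stop("tautomer enumeration requires a neutral molecule; standardize() first")
  start <- canonical_smiles(mol)
  if (is.na(start)) stop("invalid input structure for tautomer enumeration")
  ref_formula <- mol_formula(parse_smiles(start))
  seen <- start
  queue <- start
  while (length(queue) > 0L && length(seen) < max_tautomers) {
    smi <- queue[1]; queue <- queue[-1]
    m <- tryCatch(parse_smiles(smi), error = function(e) NULL)
    if (is.null(m)) next
    for (rule in .tautomer_rules) {
      for (e in rule(m)) {
        can <- canonical_smiles(e)
        if (is.na(can) || can %in% seen) next
        chk <- tryCatch(parse_smiles(can), error = function(e) NULL)
        if (is.null(chk) || mol_net_charge(chk) != 0L ||
            !identical(mol_formula(chk), ref_formula)) next
        if (length(seen) >= max_tautomers) {
          mp_log("warn", "tautomer",
                 sprintf("tautomer cap %d reached; enumeration truncated",
                         max_tautomers), mol$id)
          break
        }
        seen <- c(seen, can)
        queue <- c(queue, can)
      }
    }
  }
  lapply(seen, function(s) {
    r <- parse_smiles(s, id = mol$id)
    r$smiles <- s
    r
  })
}

#' Select the most stable tautomer by backend energy
#'
#' Computes the total energy of every tautomer in implicit water and keeps
#' the argmin; exact ties break to the lexicographically smallest canonical
#' SMILES. Tautomers whose energy evaluation fails are excluded with a
#' warning, unless the input form itself (element 1) fails, which is an
#' error.
#'
#' @param tautomers Non-empty list of `mol_record`s (from
#'   [enumerate_tautomers()]).
#' @param backend `"mock"` or `"gfn2xtb"`.
#' @return Object of class `tautomer_set`: `parent_id`, `tautomers`,
#'   `energies` (Hartree), `selected_index`.
#' @export
select_stable_tautomer <- function(tautomers, backend = "mock") {
  stopifnot(length(tautomers) >= 1L)
  energies <- rep(NA_real_, length(tautomers))
  for (k in seq_along(tautomers)) {
    energies[k] <- tryCatch(
      compute_qm(tautomers[[k]], backend)$total_energy,
      error = function(e) {
        if (k == 1L) stop("energy evaluation failed for the input form: ",
                          conditionMessage(e))
        mp_log("warn", "tautomer", sprintf(
          "energy failed for tautomer %s; excluded",
          tautomers[[k]]$smiles))
        NA_real_
      })
  }
  ok <- which(is.finite(energies))
  if (length(ok) == 0L) stop("all tautomer energy evaluations failed")
  emin <- min(energies[ok])
  cand <- ok[energies[ok] <= emin + 1e-12]
  if (length(cand) > 1L) {
    smis <- vapply(tautomers[cand], function(t) t$smiles %||% "", "")
    cand <- cand[order(smis)][1]
  } else cand <- cand[1]
  structure(list(parent_id = tautomers[[1]]$id,
                 tautomers = tautomers,
                 energies = energies,
                 selected_index = cand),
            class = "tautomer_set")
}

#' Run the full tautomer step: enumerate, score, select
#'
#' @param mol Standardized neutral `mol_record`.
#' @param backend Energy backend.
#' @param max_tautomers Enumeration cap.
#' @return The selected tautomer as a standardized `mol_record` (explicit
#'   hydrogens, conformer), with the full `tautomer_set` attached as
#'   attribute `"tautomer_set"` for audit.
#' @export
select_tautomer <- function(mol, backend = "mock", max_tautomers = 64L) {
  ts <- select_stable_tautomer(enumerate_tautomers(mol, max_tautomers),
                               backend)
  best <- ts$tautomers[[ts$selected_index]]
  out <- standardize(best)
  attr(out, "tautomer_set") <- ts
  out
}
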