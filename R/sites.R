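# Reaction-site generation and labelling. Protomer/deprotomer structures are
# produced by direct graph edits at candidate atoms; candidates are filtered
# by (a) the structural-change rule -- the product must differ from the
# parent by exactly one proton -- and (b) a 10 eV energy window above the
# lowest-energy product of the same reaction. Training labels come from the
# package's documented ionizable-group pattern set plus those two filters
# (a desk-scale label generator standing in for exhaustive semiempirical
# site screening).

site_edit_error <- function(msg) {
  stop(structure(class = c("site_edit_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# lone pairs available on an atom given element and formal charge
.lone_pairs_now <- function(element, charge) {
  base <- ifelse(element %in% names(.LONEPAIRS), .LONEPAIRS[element], 0)
  pmax(0, base - pmax(0, charge))
}

#' Protonate a molecule at a specific atom
#'
#' Adds one hydrogen bonded to the atom and raises its formal charge by one.
#' The atom must have a lone pair available (N, O, S, P, halogen not already
#' cationic) or free valence; otherwise a `site_edit_error` is raised. The
#' product keeps the parent's atom order (new H appended) and gets a fresh
#' canonical SMILES and conformer.
#'
#' @param mol Standardized `mol_record` (explicit hydrogens).
#' @param atom_index 0-based atom index (the package-wide convention for all
#'   user-facing indices).
#' @return Protonated `mol_record` with net charge +1 relative to input.
#' @export
protonate_at <- function(mol, atom_index) {
  idx <- as.integer(atom_index) + 1L
  stopifnot(idx >= 1L, idx <= n_atoms(mol))
  el <- mol$atoms$element[idx]
  chg <- mol$atoms$charge[idx]
  lp <- .lone_pairs_now(el, chg)
  # a negatively charged atom is protonated by neutralization of the charge
  free_valence <- chg < 0L
  if (lp <= 0 && !free_valence)
    site_edit_error(sprintf(
      "atom %d (%s) has no lone pair or free valence to accept a proton",
      atom_index, el))
  out <- mol
  out$atoms <- rbind(out$atoms, data.frame(
    element = "H", charge = 0L, nH = 0L, aromatic = FALSE, chiral = 0L,
    stringsAsFactors = FALSE))
  out$bonds <- rbind(out$bonds,
                     data.frame(i = idx, j = n_atoms(out), order = 1))
  out$chiral_nbrs <- c(out$chiral_nbrs, list(NULL))
  out$atoms$charge[idx] <- chg + 1L
  can <- canonical_smiles(out)
  if (is.na(can))
    site_edit_error(sprintf("protonation at atom %d gives an invalid structure",
                            atom_index))
  out$smiles <- can
  out$id <- paste0(mol$id %||% "mol", "_prot", atom_index)
  embed_conformer(out)
}

#' Deprotonate a molecule at a specific atom
#'
#' Removes one hydrogen (explicit or implicit) from the atom and lowers its
#' formal charge by one. `site_edit_error` if the atom bears no hydrogen.
#'
#' @inheritParams protonate_at
#' @return Deprotonated `mol_record` with net charge -1 relative to input.
#' @export
deprotonate_at <- function(mol, atom_index) {
  idx <- as.integer(atom_index) + 1L
  stopifnot(idx >= 1L, idx <= n_atoms(mol))
  nb <- mol_neighbors(mol)
  hs <- nb[[idx]][mol$atoms$element[nb[[idx]]] == "H"]
  out <- mol
  if (length(hs) > 0L) {
    out$atoms$charge[idx] <- out$atoms$charge[idx] - 1L
    out <- mol_subset(out, setdiff(seq_len(n_atoms(out)), max(hs)))
  } else if (mol$atoms$nH[idx] >= 1L) {
    out$atoms$nH[idx] <- out$atoms$nH[idx] - 1L
    out$atoms$charge[idx] <- out$atoms$charge[idx] - 1L
  } else {
    site_edit_error(sprintf("atom %d (%s) bears no hydrogen",
                            atom_index, mol$atoms$element[idx]))
  }
  can <- canonical_smiles(out)
  if (is.na(can))
    site_edit_error(sprintf(
      "deprotonation at atom %d gives an invalid structure", atom_index))
  out$smiles <- can
  out$id <- paste0(mol$id %||% "mol", "_deprot", atom_index)
  embed_conformer(out)
}

#' Structural-change filter
#'
#' TRUE iff the protonated form, after deleting the transferred proton,
#' is graph-isomorphic to the other form with identical heavy-atom
#' connectivity and bond orders -- i.e. the two structures differ by exactly
#' one proton and nothing else (no ring closure/opening, no rearrangement).
#'
#' @param parent,child `mol_record`s related by one (de)protonation.
#' @param reaction `"protonation"` (child = parent + H+) or
#'   `"deprotonation"` (child = parent - H+).
#' @return Logical.
#' @export
structural_change_filter <- function(parent, child,
                                     reaction = c("protonation",
                                                  "deprotonation")) {
  reaction <- match.arg(reaction)
  want <- if (reaction == "protonation") 1L else -1L
  if (mol_net_charge(child) - mol_net_charge(parent) != want) return(FALSE)
  hp <- strip_explicit_h(parent)
  hc <- strip_explicit_h(child)
  if (n_atoms(hp) != n_atoms(hc)) return(FALSE)
  isos <- heavy_isomorphisms(hp, hc)
  if (length(isos) == 0L) return(FALSE)
  nbp <- mol_neighbors(hp); nbc <- mol_neighbors(hc)
  th <- function(m, nb) vapply(seq_len(n_atoms(m)), function(i)
    m$atoms$nH[i] + sum(m$atoms$element[nb[[i]]] == "H"), 0L)
  hP <- th(hp, nbp); hC <- th(hc, nbc)
  for (map in isos) {
    d <- hC[map] - hP
    if (sum(d) == want && sum(d != 0L) == 1L) return(TRUE)
  }
  FALSE
}

#' Energy-window filter for site candidates
#'
#' Keeps candidates whose energy lies within `window_ev` (inclusive) of the
#' lowest-energy candidate of the same reaction; order preserved.
#'
#' @param candidates List of site candidates (as built by
#'   [site_candidates()]), each with `rel_energy_ev`.
#' @param window_ev Window in eV (default 10).
#' @return Filtered list.
#' @export
energy_window_filter <- function(candidates, window_ev = 10.0) {
  if (length(candidates) == 0L) return(candidates)
  keep <- vapply(candidates, function(cc) cc$rel_energy_ev <= window_ev, TRUE)
  candidates[keep]
}

#' Build site candidates for one reaction
#'
#' Edits the molecule at each requested atom, drops edits that fail
#' structurally (invalid valence or structural change), computes backend
#' energies, and attaches the energy of each product relative to the
#' lowest-energy product of the same reaction (eV, >= 0).
#'
#' @param mol Standardized `mol_record`.
#' @param atom_indices 0-based candidate atom indices.
#' @param reaction `"protonation"` or `"deprotonation"`.
#' @param backend Energy backend.
#' @return List of site candidates: `atom_index` (0-based), `reaction`,
#'   `product` (`mol_record`), `energy` (Hartree), `rel_energy_ev`.
#' @export
site_candidates <- function(mol, atom_indices,
                            reaction = c("protonation", "deprotonation"),
                            backend = "mock") {
  reaction <- match.arg(reaction)
  edit <- if (reaction == "protonation") protonate_at else deprotonate_at
  cands <- list()
  for (ai in atom_indices) {
    prod <- tryCatch(edit(mol, ai), site_edit_error = function(e) NULL)
    if (is.null(prod)) next
    if (!structural_change_filter(mol, prod, reaction)) {
      mp_log("info", "sites", sprintf(
        "edit at atom %d rejected by structural-change filter", ai), mol$id)
      next
    }
    en <- tryCatch(compute_qm(prod, backend)$total_energy,
                   error = function(e) NA_real_)
    if (!is.finite(en)) next
    cands[[length(cands) + 1L]] <- list(atom_index = as.integer(ai),
                                        reaction = reaction, product = prod,
                                        energy = en)
  }
  if (length(cands) == 0L) return(cands)
  emin <- min(vapply(cands, `[[`, 0, "energy"))
  for (k in seq_along(cands))
    cands[[k]]$rel_energy_ev <- relative_energy_ev(emin, cands[[k]]$energy)
  cands
}

#' Load the ionizable-group pattern set
#'
#' Plain-text file, one pattern per line: `SMARTS  reaction  class`
#' (whitespace separated; `#` comments). `reaction` is `acidic`
#' (deprotonation site) or `basic` (protonation site); by convention the
#' pattern's first atom is the site atom.
#'
#' @param path Pattern file; default: the set shipped with the package.
#' @return Object of class `pattern_set`.
#' @export
load_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ionizable_patterns.smarts",
                        package = "micropka")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nchar(lines) > 0L]
  pats <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    stopifnot(length(parts) == 3L, parts[2] %in% c("acidic", "basic"))
    list(smarts = parts[1], reaction = parts[2], class = parts[3],
         compiled = compile_smarts(parts[1]))
  })
  structure(pats, class = "pattern_set")
}

# Basic-site exclusion rule (documented): an N-type protonation site
# directly bonded to a carbon or sulfur that carries a double-bonded O is an
# amide/sulfonamide-like nitrogen and is not labelled basic.
.is_amide_like_n <- function(m, idx, bm) {
  if (m$atoms$element[idx] != "N") return(FALSE)
  for (b in which(bm[idx, ] >= 1)) {
    if (!m$atoms$element[b] %in% c("C", "S")) next
    if (any(bm[b, ] == 2 & m$atoms$element == "O")) return(TRUE)
  }
  FALSE
}

#' Oracle site labels from the pattern set
#'
#' Matches the acidic and basic patterns, applies the exclusion rule for
#' amide-like nitrogens, verifies every candidate edit against the
#' structural-change filter and the energy window, and returns one binary
#' label vector per reaction (length = atom count of `mol`, explicit
#' hydrogens labelled 0). Details of each retained site (pattern class,
#' relative energy, product SMILES) are attached as attribute `"sites"`.
#'
#' @param mol Standardized neutral `mol_record`.
#' @param patterns A `pattern_set` (default: shipped set).
#' @param backend Energy backend.
#' @param window_ev Energy window (eV).
#' @return List with elements `protonation` and `deprotonation`, each a
#'   `site_label_set`: `mol_id`, `labels` (0/1 integer vector), `reaction`.
#' @export
oracle_label <- function(mol, patterns = load_patterns(), backend = "mock",
                         window_ev = 10.0) {
  n <- n_atoms(mol)
  heavy <- strip_explicit_h(mol)
  ctx <- match_context(heavy)
  bm <- ctx$bm
  hits <- list(acidic = list(), basic = list())
  for (p in patterns) {
    sites <- tryCatch(match_sites(p$compiled, heavy, ctx),
                      error = function(e) integer())
    for (s in sites) {
      if (p$reaction == "basic" && .is_amide_like_n(heavy, s, bm)) next
      key <- as.character(s)
      if (is.null(hits[[p$reaction]][[key]]))
        hits[[p$reaction]][[key]] <- p$class  # first pattern in file wins
    }
  }
  detail <- list()
  labels <- list(protonation = integer(n), deprotonation = integer(n))
  for (reaction in c("protonation", "deprotonation")) {
    side <- if (reaction == "protonation") "basic" else "acidic"
    atoms0 <- as.integer(names(hits[[side]])) - 1L  # to 0-based
    if (length(atoms0) == 0L) next
    cands <- site_candidates(mol, atoms0, reaction, backend)
    cands <- energy_window_filter(cands, window_ev)
    for (cc in cands) {
      labels[[reaction]][cc$atom_index + 1L] <- 1L
      detail[[length(detail) + 1L]] <- data.frame(
        atom_index = cc$atom_index, reaction = reaction,
        class = hits[[side]][[as.character(cc$atom_index + 1L)]],
        rel_energy_ev = cc$rel_energy_ev, energy = cc$energy,
        product_smiles = cc$product$smiles, stringsAsFactors = FALSE)
    }
  }
  out <- list(
    protonation = structure(list(mol_id = mol$id, labels = labels$protonation,
                                 reaction = "protonation"),
                            class = "site_label_set"),
    deprotonation = structure(list(mol_id = mol$id,
                                   labels = labels$deprotonation,
                                   reaction = "deprotonation"),
                              class = "site_label_set"))
  attr(out, "sites") <- if (length(detail)) do.call(rbind, detail) else
    data.frame(atom_index = integer(), reaction = character(),
               class = character(), rel_energy_ev = numeric(),
               energy = numeric(), product_smiles = character())
  out
}
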