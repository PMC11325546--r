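# SMILES reading and writing for the molecular-graph core. The parser covers
# the dialect OpenBabel emits for organic molecules: organic-subset atoms,
# bracket atoms with isotope/charge/H-count/tetrahedral stereo, branches,
# ring-closure digits (incl. %nn), aromatic lowercase atoms, and '.'
# separated fragments. Directional (E/Z) bond markers '/' and '\' are parsed
# as plain single bonds; only tetrahedral stereo is tracked. Canonical forms
# are produced by OpenBabel, so this writer only needs to emit *valid*
# SMILES, not canonical ones.

TWO_LETTER <- c("Cl", "Br", "Si", "Se", "As", "Na", "Li", "Mg", "Ca", "Fe",
                "Zn", "Cu", "Mn", "Co", "Ni", "Al", "Sn", "Te", "Sb")

#' Parse a SMILES string into a molecular record
#'
#' @param s SMILES string (single molecule; dot-separated fragments allowed).
#' @param id Identifier to attach.
#' @return `mol_record`, or an error for malformed input.
#' @export
parse_smiles <- function(s, id = NA_character_) {
  s <- trimws(s)
  if (nchar(s) == 0L) stop("empty SMILES string")
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- list(); bonds <- list()
  nbr <- list()        # neighbour order per atom (0 = implicit H)
  prev <- 0L           # previous atom index (0 = none / after '.')
  pend <- NA_real_     # pending explicit bond order
  stack <- integer()
  rings <- list()      # open ring closures: key -> list(atom, order, slot)
  pos <- 1L

  new_atom <- function(element, aromatic, charge, nH, chiral, bracket) {
    a <- length(atoms) + 1L
    atoms[[a]] <<- list(element = element, charge = as.integer(charge),
                        nH = as.integer(nH), aromatic = aromatic,
                        chiral = as.integer(chiral), bracket = bracket)
    nbr[[a]] <<- integer()
    if (prev > 0L) {
      ord <- if (!is.na(pend)) pend else
        if (aromatic && atoms[[prev]]$aromatic) 1.5 else 1
      bonds[[length(bonds) + 1L]] <<- c(prev, a, ord)
      nbr[[prev]] <<- c(nbr[[prev]], a)
      nbr[[a]] <<- c(nbr[[a]], prev)
    }
    if (bracket && nH == 1L && chiral > 0L) nbr[[a]] <<- c(nbr[[a]], 0L)
    pend <<- NA_real_
    prev <<- a
    a
  }

  close_ring <- function(key) {
    a <- prev
    if (a == 0L) stop("ring digit with no preceding atom: ", s)
    ord_here <- pend; pend <<- NA_real_
    if (!is.null(rings[[key]])) {
      op <- rings[[key]]
      rings[[key]] <<- NULL
      ord <- if (!is.na(ord_here)) ord_here else if (!is.na(op$order)) op$order
        else if (atoms[[a]]$aromatic && atoms[[op$atom]]$aromatic) 1.5 else 1
      bonds[[length(bonds) + 1L]] <<- c(op$atom, a, ord)
      # fill the placeholder slot recorded when the digit was opened
      nbr[[op$atom]][op$slot] <<- a
      nbr[[a]] <<- c(nbr[[a]], op$atom)
    } else {
      nbr[[a]] <<- c(nbr[[a]], NA_integer_)  # placeholder, filled on close
      rings[[key]] <<- list(atom = a, order = if (is.na(ord_here))
        NA_real_ else ord_here, slot = length(nbr[[a]]))
    }
  }

  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "[") {
      close_br <- pos
      while (close_br <= n && chars[close_br] != "]") close_br <- close_br + 1L
      if (close_br > n) stop("unclosed bracket atom in SMILES: ", s)
      body <- substr(s, pos + 1L, close_br - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\+{2,}|-{2,})?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) stop("cannot parse bracket atom [", body, "]")
      sym <- m[3]
      if (sym == "*") stop("wildcard atom not supported in molecules: ", s)
      aromatic <- sym == tolower(sym) && sym %in%
        c("b", "c", "n", "o", "p", "s", "se", "as")
      element <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      chiral <- if (m[4] == "@") 1L else if (m[4] == "@@") 2L else 0L
      nH <- if (m[5] == "") 0L else if (m[5] == "H") 1L else
        as.integer(substring(m[5], 2))
      chg <- m[6]
      charge <- if (chg == "") 0L
        else if (chg == "+") 1L else if (chg == "-") -1L
        else if (grepl("^\\++$", chg)) nchar(chg)
        else if (grepl("^-+$", chg)) -nchar(chg)
        else as.integer(chg)
      new_atom(element, aromatic, charge, nH, chiral, bracket = TRUE)
      pos <- close_br + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                     "/" = 1, "\\" = 1)
      pos <- pos + 1L
    } else if (ch == "(") {
      if (prev == 0L) stop("branch with no root atom: ", s)
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch == ".") {
      prev <- 0L; pend <- NA_real_; pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); pos <- pos + 1L
    } else if (ch == "%") {
      key <- substr(s, pos + 1L, pos + 2L)
      if (!grepl("^[0-9]{2}$", key)) stop("bad %nn ring closure in: ", s)
      close_ring(key); pos <- pos + 3L
    } else {
      two <- substr(s, pos, pos + 1L)
      if (two %in% TWO_LETTER) {
        new_atom(two, FALSE, 0L, NA_integer_, 0L, bracket = FALSE)
        pos <- pos + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        new_atom(ch, FALSE, 0L, NA_integer_, 0L, bracket = FALSE)
        pos <- pos + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        new_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L, bracket = FALSE)
        pos <- pos + 1L
      } else stop("unexpected character '", ch, "' in SMILES: ", s)
    }
  }
  if (length(rings) > 0L) stop("unmatched ring bonds in SMILES: ", s)
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES: ", s)
  if (length(atoms) == 0L) stop("no atoms parsed from SMILES: ", s)

  at <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    nH = vapply(atoms, `[[`, 0L, "nH"),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    chiral = vapply(atoms, `[[`, 0L, "chiral"),
    stringsAsFactors = FALSE)
  bd <- if (length(bonds)) {
    bm <- do.call(rbind, bonds)
    data.frame(i = as.integer(bm[, 1]), j = as.integer(bm[, 2]),
               order = bm[, 3])
  } else data.frame(i = integer(), j = integer(), order = numeric())

  # implicit H for bare atoms by standard valence rules
  bare <- which(is.na(at$nH))
  for (a in bare) {
    sel <- bd$i == a | bd$j == a
    at$nH[a] <- implicit_h_for(at$element[a], at$aromatic[a], bd$order[sel])
  }
  cn <- lapply(seq_along(nbr), function(a) {
    if (at$chiral[a] > 0L) as.integer(nbr[[a]]) else NULL
  })
  mol_new(at, bd, id = id, chiral_nbrs = cn)
}

# parity of the permutation taking `from` ordering to `to` ordering
perm_parity <- function(from, to) {
  p <- match(to, from)
  if (anyNA(p)) return(NA_integer_)
  inv <- 0L
  np <- length(p)
  if (np > 1L) for (a in 1:(np - 1L)) for (b in (a + 1L):np)
    if (p[a] > p[b]) inv <- inv + 1L
  inv %% 2L
}

#' Write a molecular record as a SMILES string
#'
#' Emits valid (not canonical) SMILES; canonicalization is OpenBabel's job.
#' Tetrahedral stereo is written with parity adjusted to the output
#' neighbour order; stereo centres whose reference list cannot be matched
#' (e.g. after unrecorded edits) are silently written achiral.
#'
#' @param mol A `mol_record`.
#' @return SMILES string.
#' @export
write_smiles <- function(mol) {
  n <- n_atoms(mol)
  nb <- mol_neighbors(mol)
  bm <- mol_bond_matrix(mol)
  visited <- rep(FALSE, n)
  # ---- plan pass: DFS tree + ring-closure bonds -----------------------
  children <- vector("list", n)
  parent <- rep(0L, n)
  closures <- list()  # list of (first, second, order)
  used <- matrix(FALSE, n, n)
  roots <- integer()
  for (root in seq_len(n)) {
    if (visited[root]) next
    roots <- c(roots, root)
    st <- root; visited[root] <- TRUE
    order_stack <- list(root)
    while (length(order_stack)) {
      v <- order_stack[[1]]; order_stack <- order_stack[-1]
      for (w in nb[[v]]) {
        if (used[v, w]) next
        used[v, w] <- used[w, v] <- TRUE
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          children[[v]] <- c(children[[v]], w)
          order_stack <- c(list(w), order_stack)  # depth-first
        } else {
          closures[[length(closures) + 1L]] <- c(v, w, bm[v, w])
        }
      }
    }
  }
  ring_digit <- function(k) if (k <= 9) as.character(k) else sprintf("%%%02d", k)
  at_open <- vector("list", n)   # closure tokens per atom in digit order
  at_nbr_ring <- vector("list", n)  # ring partner per atom in digit order
  if (length(closures)) for (k in seq_along(closures)) {
    cl <- closures[[k]]
    sym <- if (cl[3] == 2) "=" else if (cl[3] == 3) "#" else ""
    for (side in 1:2) {
      a <- cl[side]; b <- cl[3 - side]
      at_open[[a]] <- c(at_open[[a]], paste0(sym, ring_digit(k)))
      at_nbr_ring[[a]] <- c(at_nbr_ring[[a]], b)
    }
  }

  atom_token <- function(v, written_order) {
    el <- mol$atoms$element[v]
    arom <- mol$atoms$aromatic[v]
    chg <- mol$atoms$charge[v]
    nH <- mol$atoms$nH[v]
    chiral <- mol$atoms$chiral[v]
    tag <- ""
    if (chiral > 0L && !is.null(mol$chiral_nbrs[[v]])) {
      par <- perm_parity(mol$chiral_nbrs[[v]], written_order)
      if (!is.na(par)) {
        eff <- if (par == 0L) chiral else 3L - chiral
        tag <- if (eff == 1L) "@" else "@@"
      }
    }
    sym <- if (arom) tolower(el) else el
    bare_ok <- tag == "" && chg == 0L && el != "H" &&
      el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I") &&
      nH == mol_default_nH(mol, v)
    if (bare_ok) return(sym)
    htok <- if (nH == 0L) "" else if (nH == 1L) "H" else paste0("H", nH)
    ctok <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
      else sprintf("%+d", chg)
    paste0("[", sym, tag, htok, ctok, "]")
  }

  bond_sym <- function(v, w) {
    o <- bm[v, w]
    if (o == 2) return("=")
    if (o == 3) return("#")
    if (o == 1.5) return("")  # aromatic default between aromatic atoms
    if (mol$atoms$aromatic[v] && mol$atoms$aromatic[w]) return("-")
    ""
  }

  emit <- function(v) {
    # output neighbour order for stereo: parent, implicit H (if bracketed
    # with H1), ring partners in digit order, then children in written order
    wo <- integer()
    if (parent[v] > 0L) wo <- c(wo, parent[v])
    if (mol$atoms$nH[v] == 1L && mol$atoms$chiral[v] > 0L) wo <- c(wo, 0L)
    wo <- c(wo, at_nbr_ring[[v]] %||% integer(), children[[v]] %||% integer())
    out <- atom_token(v, wo)
    if (!is.null(at_open[[v]])) out <- paste0(out, paste(at_open[[v]],
                                                         collapse = ""))
    ch <- children[[v]]
    if (!is.null(ch) && length(ch)) {
      nc <- length(ch)
      for (k in seq_len(nc)) {
        sub <- paste0(bond_sym(v, ch[k]), emit(ch[k]))
        out <- paste0(out, if (k < nc) paste0("(", sub, ")") else sub)
      }
    }
    out
  }

  paste(vapply(roots, emit, ""), collapse = ".")
}

#' Canonical SMILES via OpenBabel
#'
#' @param smi SMILES string.
#' @return Canonical SMILES, or `NA_character_` if OpenBabel rejects the
#'   input.
#' @export
ob_canonical <- function(smi) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smi)),
    error = function(e) "")
  out <- sub("[ \t].*$", "", trimws(out))
  if (nchar(out) == 0L) NA_character_ else out
}

#' Canonical SMILES of a molecular record
#'
#' Writes the record as SMILES and canonicalizes through OpenBabel. Explicit
#' hydrogens are folded to implicit form first so the canonical string is the
#' conventional heavy-atom SMILES.
#'
#' @param mol A `mol_record`.
#' @return Canonical SMILES string, or `NA_character_` for invalid graphs.
#' @export
canonical_smiles <- function(mol) {
  ob_canonical(write_smiles(strip_explicit_h(mol)))
}

# Canonical SMILES with tetrahedral stereo marks removed; identical for
# enantiomers. Used to seed deterministic, mirror-agnostic computations.
achiral_smiles <- function(mol_or_smiles) {
  s <- if (inherits(mol_or_smiles, "mol_record")) {
    if (!is.null(mol_or_smiles$smiles) && !is.na(mol_or_smiles$smiles))
      mol_or_smiles$smiles else canonical_smiles(mol_or_smiles)
  } else mol_or_smiles
  if (is.na(s)) return(NA_character_)
  if (!grepl("@", s, fixed = TRUE)) return(s)  # already stereo-free
  ob_canonical(gsub("@", "", s, fixed = TRUE))
}

#' Parse a SMILES string in OpenBabel-canonical atom order
#'
#' Canonicalizes first, then parses the canonical string, so equal molecules
#' always yield records with identical atom ordering.
#'
#' @param smi SMILES string.
#' @param id Identifier.
#' @return `mol_record` with the `smiles` field set, or `NULL` if the SMILES
#'   is invalid.
#' @export
mol_from_smiles <- function(smi, id = NA_character_) {
  can <- ob_canonical(smi)
  if (is.na(can)) return(NULL)
  m <- tryCatch(parse_smiles(can, id = id), error = function(e) NULL)
  if (is.null(m)) return(NULL)
  m$smiles <- can
  m
}
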