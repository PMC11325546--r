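# Substructure matching. Implements a documented subset of the SMARTS
# pattern language -- enough to express the ionizable-group patterns shipped
# with the package -- plus exact graph isomorphism used by the
# structural-change filter. Patterns are matched against the implicit-H
# (heavy atom) form of a molecule.
#
# Supported SMARTS subset:
#   atoms:  C N O S P F Cl Br I B (aliphatic), c n o s p (aromatic),
#           A (aliphatic any), a (aromatic any), * (any), or a bracket
#           expression combining primitives with ! (not), & or juxtaposition
#           (and), , (or), ; (low-precedence and):
#           element symbols, #<n> atomic number, H<n> total hydrogen count,
#           D<n> heavy-atom degree, X<n> total connections (heavy + H),
#           R / R0 (ring / not), r<n> smallest ring size, +<n> / -<n> charge,
#           a / A.
#   bonds:  - = # : ~ (any), default single-or-aromatic.
#   branches and ring-closure digits as in SMILES.
# Not supported (and not needed by the shipped patterns): recursive SMARTS
# $(...), atom maps, stereo, @/@@, low-precedence or.

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                   Cl = 17, Br = 35, I = 53)

# --- pattern compilation ---------------------------------------------------

# Compile one atom-primitive token into a predicate over the match context.
compile_primitive <- function(tok) {
  if (grepl("^#[0-9]+$", tok)) {
    z <- as.integer(substring(tok, 2))
    return(function(ctx, i) ctx$z[i] == z)
  }
  if (tok == "*") return(function(ctx, i) TRUE)
  if (tok == "A") return(function(ctx, i) !ctx$aromatic[i])
  if (tok == "a") return(function(ctx, i) ctx$aromatic[i])
  if (grepl("^H[0-9]*$", tok)) {
    hn <- if (tok == "H") 1L else as.integer(substring(tok, 2))
    return(function(ctx, i) ctx$totalH[i] == hn)
  }
  if (grepl("^D[0-9]+$", tok)) {
    d <- as.integer(substring(tok, 2))
    return(function(ctx, i) ctx$degree[i] == d)
  }
  if (grepl("^X[0-9]+$", tok)) {
    x <- as.integer(substring(tok, 2))
    return(function(ctx, i) ctx$conn[i] == x)
  }
  if (tok == "R") return(function(ctx, i) ctx$ring[i])
  if (tok == "R0") return(function(ctx, i) !ctx$ring[i])
  if (grepl("^r[0-9]+$", tok)) {
    r <- as.integer(substring(tok, 2))
    return(function(ctx, i) ctx$ring_size[i] == r)
  }
  if (grepl("^[+-][0-9]*$", tok)) {
    chg <- if (tok == "+") 1L else if (tok == "-") -1L else as.integer(tok)
    return(function(ctx, i) ctx$charge[i] == chg)
  }
  # element symbol, aromatic if lowercase
  if (grepl("^[A-Z][a-z]?$", tok)) {
    el <- tok
    return(function(ctx, i) ctx$element[i] == el && !ctx$aromatic[i])
  }
  if (grepl("^[a-z][a-z]?$", tok)) {
    el <- paste0(toupper(substr(tok, 1, 1)), substring(tok, 2))
    return(function(ctx, i) ctx$element[i] == el && ctx$aromatic[i])
  }
  stop("unsupported SMARTS atom primitive: '", tok, "'")
}

# Tokenize the body of a bracket atom expression into primitive tokens,
# preserving !, &, ',' and ';' operators.
tokenize_atom_expr <- function(body) {
  toks <- character()
  i <- 1L
  n <- nchar(body)
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch %in% c("!", "&", ",", ";")) {
      toks <- c(toks, ch); i <- i + 1L
    } else if (ch == "#") {
      m <- regmatches(body, regexpr("^#[0-9]+", substring(body, i)))
      toks <- c(toks, substr(body, i, i + attr(regexpr("^#[0-9]+",
        substring(body, i)), "match.length") - 1L))
      i <- i + nchar(toks[length(toks)])
    } else if (ch %in% c("H", "D", "X", "r")) {
      m <- regmatches(substring(body, i),
                      regexpr(paste0("^", ch, "[0-9]*"), substring(body, i)))
      toks <- c(toks, m); i <- i + nchar(m)
    } else if (ch == "R") {
      m <- regmatches(substring(body, i), regexpr("^R[0-9]?",
                                                  substring(body, i)))
      toks <- c(toks, m); i <- i + nchar(m)
    } else if (ch %in% c("+", "-")) {
      m <- regmatches(substring(body, i), regexpr("^[+-][0-9]*",
                                                  substring(body, i)))
      toks <- c(toks, m); i <- i + nchar(m)
    } else {
      two <- substr(body, i, i + 1L)
      if (two %in% c(TWO_LETTER, tolower(TWO_LETTER))) {
        toks <- c(toks, two); i <- i + 2L
      } else {
        toks <- c(toks, ch); i <- i + 1L
      }
    }
  }
  toks
}

# Build predicate for a full bracket expression with SMARTS operator
# precedence: ! > and (& / juxtaposition) > , (or) > ; (and).
compile_atom_expr <- function(body) {
  toks <- tokenize_atom_expr(body)
  # split by ';'
  split_on <- function(toks, op) {
    groups <- list(); cur <- character()
    for (t in toks) {
      if (identical(t, op)) { groups[[length(groups) + 1L]] <- cur; cur <- character() }
      else cur <- c(cur, t)
    }
    groups[[length(groups) + 1L]] <- cur
    groups
  }
  and_groups <- split_on(toks, ";")
  preds_and <- lapply(and_groups, function(g) {
    or_groups <- split_on(g, ",")
    preds_or <- lapply(or_groups, function(og) {
      # sequence of primitives with optional '!' prefixes, '&' = and
      og <- og[og != "&"]
      prims <- list(); negate <- FALSE
      for (t in og) {
        if (t == "!") { negate <- TRUE; next }
        p <- compile_primitive(t)
        prims[[length(prims) + 1L]] <- if (negate) local({
          pp <- p; function(ctx, i) !pp(ctx, i)
        }) else p
        negate <- FALSE
      }
      function(ctx, i) all(vapply(prims, function(p) p(ctx, i), TRUE))
    })
    function(ctx, i) any(vapply(preds_or, function(p) p(ctx, i), TRUE))
  })
  function(ctx, i) all(vapply(preds_and, function(p) p(ctx, i), TRUE))
}

bond_pred <- function(sym) {
  switch(sym,
         "-" = function(o) o == 1,
         "=" = function(o) o == 2,
         "#" = function(o) o == 3,
         ":" = function(o) o == 1.5,
         "~" = function(o) TRUE,
         function(o) o == 1 | o == 1.5)  # default: single or aromatic
}

#' Compile a SMARTS pattern (supported subset)
#'
#' @param smarts Pattern string; the first atom is, by the package's
#'   convention, the reaction-site atom.
#' @return Compiled pattern (atom predicates + bond structure) for
#'   [match_pattern()].
#' @export
compile_smarts <- function(smarts) {
  s <- trimws(smarts)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  preds <- list(); bonds <- list()
  prev <- 0L; pend <- NULL; stack <- integer(); rings <- list()
  pos <- 1L
  new_patom <- function(pred) {
    a <- length(preds) + 1L
    preds[[a]] <<- pred
    if (prev > 0L) {
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = a,
                                           pred = bond_pred(pend %||% ""))
    }
    pend <<- NULL
    prev <<- a
    a
  }
  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "[") {
      close_br <- pos
      depth <- 0L
      repeat {
        if (chars[close_br] == "[") depth <- depth + 1L
        if (chars[close_br] == "]") { depth <- depth - 1L
          if (depth == 0L) break }
        close_br <- close_br + 1L
        if (close_br > n) stop("unclosed bracket in SMARTS: ", s)
      }
      body <- substr(s, pos + 1L, close_br - 1L)
      if (grepl("$(", body, fixed = TRUE))
        stop("recursive SMARTS not supported: ", s)
      new_patom(compile_atom_expr(body))
      pos <- close_br + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pend <- ch; pos <- pos + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]; rings[[key]] <- NULL
        bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev,
                                            pred = bond_pred(op$sym %||%
                                                               pend %||% ""))
      } else rings[[key]] <- list(atom = prev, sym = pend)
      pend <- NULL
      pos <- pos + 1L
    } else {
      two <- substr(s, pos, pos + 1L)
      if (two %in% c("Cl", "Br")) {
        new_patom(compile_atom_expr(two)); pos <- pos + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I", "A",
                           "b", "c", "n", "o", "p", "s", "a", "*")) {
        new_patom(compile_atom_expr(ch)); pos <- pos + 1L
      } else stop("unexpected character '", ch, "' in SMARTS: ", s)
    }
  }
  if (length(rings)) stop("unmatched ring closure in SMARTS: ", s)
  structure(list(smarts = s, preds = preds, bonds = bonds),
            class = "smarts_pattern")
}

# Per-molecule match context (on the implicit-H heavy graph).
match_context <- function(mol) {
  nb <- mol_neighbors(mol)
  el <- mol$atoms$element
  degree <- vapply(nb, length, 1L)
  totalH <- vapply(seq_len(n_atoms(mol)), function(i)
    mol$atoms$nH[i] + sum(el[nb[[i]]] == "H"), 0L)
  list(element = el,
       z = unname(ifelse(el %in% names(ATOMIC_NUMBER), ATOMIC_NUMBER[el], 0)),
       aromatic = mol$atoms$aromatic,
       charge = mol$atoms$charge,
       totalH = as.integer(totalH),
       degree = degree,
       conn = degree + mol$atoms$nH,
       ring = ring_atom_flags(mol),
       ring_size = smallest_ring_sizes(mol),
       nb = nb,
       bm = mol_bond_matrix(mol))
}

#' Match a compiled SMARTS pattern against a molecule
#'
#' Backtracking subgraph monomorphism on the implicit-hydrogen graph.
#'
#' @param pattern Result of [compile_smarts()].
#' @param mol A `mol_record` (explicit hydrogens are stripped internally).
#' @param ctx Optional precomputed [match_context()] of the stripped form.
#' @param max_matches Enumeration cap.
#' @return List of integer vectors (pattern atom -> molecule atom, 1-based,
#'   on the stripped heavy-atom graph, whose heavy-atom order equals the
#'   input's).
#' @export
match_pattern <- function(pattern, mol, ctx = NULL, max_matches = 1000L) {
  m <- strip_explicit_h(mol)
  if (is.null(ctx)) ctx <- match_context(m)
  np <- length(pattern$preds)
  # adjacency of pattern
  padj <- vector("list", np)
  for (b in pattern$bonds) {
    padj[[b$i]] <- c(padj[[b$i]], list(b))
    padj[[b$j]] <- c(padj[[b$j]], list(list(i = b$j, j = b$i, pred = b$pred)))
  }
  # order pattern atoms so each (after the first) touches a previous one
  order_idx <- 1L
  seen <- c(TRUE, rep(FALSE, np - 1L))
  while (length(order_idx) < np) {
    added <- FALSE
    for (a in order_idx) for (e in padj[[a]]) if (!seen[e$j]) {
      order_idx <- c(order_idx, e$j); seen[e$j] <- TRUE; added <- TRUE
    }
    if (!added) {  # disconnected pattern: append rest
      rest <- which(!seen)[1]
      order_idx <- c(order_idx, rest); seen[rest] <- TRUE
    }
  }
  matches <- list()
  nmol <- length(ctx$element)
  map <- rep(0L, np)
  used <- rep(FALSE, nmol)
  recurse <- function(k) {
    if (length(matches) >= max_matches) return()
    if (k > np) { matches[[length(matches) + 1L]] <<- map; return() }
    pa <- order_idx[k]
    for (cand in seq_len(nmol)) {
      if (used[cand]) next
      if (!pattern$preds[[pa]](ctx, cand)) next
      ok <- TRUE
      for (e in padj[[pa]]) {
        other <- map[e$j]
        if (other == 0L) next
        o <- ctx$bm[cand, other]
        if (o == 0 || !e$pred(o)) { ok <- FALSE; break }
      }
      if (!ok) next
      map[pa] <<- cand; used[cand] <<- TRUE
      recurse(k + 1L)
      map[pa] <<- 0L; used[cand] <<- FALSE
    }
  }
  recurse(1L)
  matches
}

#' Atoms matching the first (site) atom of a pattern
#' @keywords internal
match_sites <- function(pattern, mol, ctx = NULL) {
  unique(vapply(match_pattern(pattern, mol, ctx), `[`, 0L, 1L))
}

# --- exact isomorphism -----------------------------------------------------

# All element+bond-order preserving isomorphisms between two heavy-atom
# graphs (explicit hydrogens stripped). Empty list if none.
heavy_isomorphisms <- function(a, b, max_matches = 2000L) {
  ha <- strip_explicit_h(a); hb <- strip_explicit_h(b)
  if (n_atoms(ha) != n_atoms(hb)) return(list())
  if (!identical(sort(ha$atoms$element), sort(hb$atoms$element)))
    return(list())
  # encode as a pattern with exact element + order predicates; require
  # equal degree so the monomorphism is an isomorphism (equal atom counts
  # and bond counts)
  if (nrow(ha$bonds) != nrow(hb$bonds)) return(list())
  nbA <- mol_neighbors(ha)
  degA <- vapply(nbA, length, 1L)
  preds <- lapply(seq_len(n_atoms(ha)), function(i) {
    el <- ha$atoms$element[i]; d <- degA[i]
    function(ctx, j) ctx$element[j] == el && ctx$degree[j] == d
  })
  bonds <- lapply(seq_len(nrow(ha$bonds)), function(k) {
    o <- ha$bonds$order[k]
    list(i = ha$bonds$i[k], j = ha$bonds$j[k],
         pred = local({ oo <- o; function(x) x == oo }))
  })
  pat <- structure(list(smarts = NA, preds = preds, bonds = bonds),
                   class = "smarts_pattern")
  match_pattern(pat, hb, max_matches = max_matches)
}
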