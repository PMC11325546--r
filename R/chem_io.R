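# Molecule input/output, standardization, filtering and enantiomer
# augmentation. Standardized records are the currency of the whole pipeline:
# largest fragment, neutralized, canonical atom order, explicit hydrogens,
# one deterministic conformer.

ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904,
                 I = 126.904)

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files contain one molecule per line, `SMILES[whitespace]name`;
#' blank lines are skipped. Invalid entries are skipped with a logged
#' warning; the number skipped is attached as attribute `n_skipped`.
#'
#' @param path File path.
#' @param format `"smiles"` or `"sdf"`.
#' @return List of `mol_record` (possibly empty), with attribute
#'   `n_skipped`.
#' @export
read_molecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read molecule file: ", path)
  records <- list()
  skipped <- 0L
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lineno <- 0L
    for (ln in lines) {
      lineno <- lineno + 1L
      ln <- trimws(ln)
      if (nchar(ln) == 0L || startsWith(ln, "#")) next
      parts <- strsplit(ln, "[ \t]+")[[1]]
      id <- if (length(parts) >= 2L) parts[2] else sprintf("mol%d", lineno)
      m <- mol_from_smiles(parts[1], id = id)
      if (is.null(m)) {
        skipped <- skipped + 1L
        mp_log("warn", "read", sprintf("line %d: invalid SMILES '%s', skipped",
                                       lineno, parts[1]))
      } else records[[length(records) + 1L]] <- m
    }
  } else {
    sdf <- tryCatch(ChemmineR::read.SDFset(path), error = function(e)
      stop("cannot read SDF file: ", path, " (", conditionMessage(e), ")"))
    ids <- ChemmineR::sdfid(sdf)
    for (k in seq_along(sdf)) {
      smi <- tryCatch(
        as.character(ChemmineR::sdf2smiles(sdf[k])), error = function(e) NA)
      m <- if (is.na(smi)) NULL else mol_from_smiles(smi, id = ids[k])
      if (is.null(m)) {
        skipped <- skipped + 1L
        mp_log("warn", "read", sprintf("SDF record %d invalid, skipped", k))
      } else records[[length(records) + 1L]] <- m
    }
  }
  attr(records, "n_skipped") <- skipped
  records
}

#' Deterministic conformer embedding
#'
#' Classical multidimensional scaling of the bond-graph distance matrix
#' (scaled by 1.5 Angstrom per bond) into three dimensions, with
#' deterministic axis-sign fixing and a small jitter drawn from a seed
#' derived from the stereo-stripped canonical SMILES. Enantiomers therefore
#' receive bit-identical coordinates, which (together with the
#' reflection-invariant shape descriptors) guarantees identical features.
#'
#' @param mol A `mol_record` (explicit hydrogens recommended).
#' @return The record with `coords` set (N x 3, Angstrom).
#' @export
embed_conformer <- function(mol) {
  n <- n_atoms(mol)
  seed_src <- achiral_smiles(mol)
  if (is.na(seed_src)) seed_src <- write_smiles(mol)
  seed <- stable_hash(seed_src)
  if (n == 1L) {
    mol$coords <- matrix(0, 1, 3)
    return(mol)
  }
  D <- graph_distances(mol) * 1.5
  k <- min(3L, n - 1L)
  xy <- suppressWarnings(stats::cmdscale(D, k = k))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 1L)
  if (ncol(xy) < 3L) xy <- cbind(xy, matrix(0, n, 3L - ncol(xy)))
  # fix eigenvector sign ambiguity: first entry of magnitude > 1e-8 positive
  for (cidx in 1:3) {
    v <- xy[, cidx]
    nz <- which(abs(v) > 1e-8)
    if (length(nz) && v[nz[1]] < 0) xy[, cidx] <- -v
  }
  jit <- with_seed(seed, matrix(stats::runif(n * 3, -0.15, 0.15), n, 3))
  mol$coords <- xy + jit
  mol
}

#' Standardize a molecule
#'
#' Keeps the largest covalent fragment (by heavy-atom count, ties broken by
#' lexicographically smallest canonical SMILES), neutralizes simple +/-1
#' protonation states (-1 on O/N/S gains a proton; +1 on an N bearing a
#' proton loses one) until the net charge is zero or no rule applies, puts
#' atoms in canonical order, adds explicit hydrogens, and embeds one
#' deterministic conformer. A fragment that cannot be neutralized is flagged
#' and passed through with a warning.
#'
#' @param mol A `mol_record`.
#' @return Standardized `mol_record`.
#' @export
standardize <- function(mol) {
  stopifnot(inherits(mol, "mol_record"))
  m <- strip_explicit_h(mol)
  # largest covalent fragment
  comp <- mol_components(m)
  if (max(comp) > 1L) {
    heavy <- m$atoms$element != "H"
    sizes <- vapply(seq_len(max(comp)), function(cc)
      sum(heavy & comp == cc), 0L)
    cand <- which(sizes == max(sizes))
    if (length(cand) > 1L) {
      smis <- vapply(cand, function(cc)
        canonical_smiles(mol_subset(m, which(comp == cc))), "")
      cand <- cand[order(smis)][1]
    } else cand <- cand[1]
    m <- mol_subset(m, which(comp == cand))
    mp_log("info", "standardize", "kept largest covalent fragment", m$id)
  }
  # simple neutralization
  repeat {
    net <- mol_net_charge(m)
    if (net == 0L) break
    if (net < 0L) {
      hit <- which(m$atoms$charge == -1L & m$atoms$element %in% c("O", "N", "S"))
      if (length(hit) == 0L) break
      a <- hit[1]
      m$atoms$charge[a] <- 0L
      m$atoms$nH[a] <- m$atoms$nH[a] + 1L
    } else {
      hit <- which(m$atoms$charge == 1L & m$atoms$element == "N" &
                     m$atoms$nH >= 1L)
      if (length(hit) == 0L) break
      a <- hit[1]
      m$atoms$charge[a] <- 0L
      m$atoms$nH[a] <- m$atoms$nH[a] - 1L
    }
  }
  flagged <- mol_net_charge(m) != 0L
  if (flagged)
    mp_log("warn", "standardize",
           sprintf("no neutralization rule for net charge %+d; passed through",
                   mol_net_charge(m)), m$id)
  can <- canonical_smiles(m)
  if (is.na(can)) stop("standardization produced an invalid structure for ",
                       m$id)
  out <- parse_smiles(can, id = m$id)
  out$smiles <- can
  out$flagged <- flagged
  out <- add_explicit_h(out)
  out$smiles <- can
  embed_conformer(out)
}

#' Organic-element filter
#'
#' @param mol A `mol_record`.
#' @return TRUE iff every atom is one of H, C, N, O, S, P, F, Cl, Br, I and
#'   the molecule contains at least one carbon.
#' @export
element_filter <- function(mol) {
  el <- mol$atoms$element
  all(el %in% ORGANIC_ELEMENTS) && any(el == "C")
}

#' Training-range pKa filter
#'
#' @param pka Numeric pKa value(s).
#' @return Logical: TRUE iff 0 <= pKa <= 14 (bounds inclusive).
#' @export
pka_range_filter <- function(pka) {
  if (any(is.nan(pka))) stop("NaN pKa passed to pka_range_filter")
  pka >= 0 & pka <= 14
}

#' Invert all tetrahedral stereocenters
#'
#' Produces the enantiomer: every tetrahedral tag is flipped and the
#' conformer is mirrored (x axis negated) rather than re-embedded, so the 3D
#' descriptors are exactly those of the mirror image. Molecules without
#' stereocenters -- and meso forms, whose inverted canonical SMILES equals
#' the original -- return `NULL` (no augmentation emitted).
#'
#' @param mol Standardized `mol_record`.
#' @return `mol_record` of the enantiomer, or `NULL`.
#' @export
invert_stereocenters <- function(mol) {
  if (!any(mol$atoms$chiral > 0L)) return(NULL)
  out <- mol
  out$atoms$chiral <- ifelse(out$atoms$chiral == 0L, 0L,
                             3L - out$atoms$chiral)
  if (!is.null(out$coords)) out$coords[, 1] <- -out$coords[, 1]
  can <- canonical_smiles(out)
  if (is.na(can) || identical(can, mol$smiles)) return(NULL)
  out$smiles <- can
  out$id <- if (is.na(mol$id)) NA_character_ else paste0(mol$id, "_ent")
  out
}

#' Write per-site pKa predictions
#'
#' CSV columns, in order: `id`, `smiles` (selected tautomer), `atom_index`
#' (0-based), `reaction`, `pka`. SDF output writes one record per site with
#' the same fields as SDF data properties.
#'
#' @param records data.frame with those five columns.
#' @param path Output path.
#' @param format `"csv"` or `"sdf"`.
#' @export
write_predictions <- function(records, path, format = c("csv", "sdf")) {
  format <- match.arg(format)
  cols <- c("id", "smiles", "atom_index", "reaction", "pka")
  if (nrow(records) > 0L) stopifnot(all(cols %in% names(records)))
  records <- if (nrow(records)) records[, cols, drop = FALSE] else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 5)), cols)
  if (format == "csv") {
    ok <- tryCatch({
      utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write predictions to ", path)
  } else {
    if (nrow(records) == 0L) stop("SDF output requires at least one record")
    sdfs <- lapply(seq_len(nrow(records)), function(k) {
      sdf <- ChemmineR::smiles2sdf(records$smiles[k])
      ChemmineR::datablock(sdf) <- list(stats::setNames(
        c(records$id[k], as.character(records$atom_index[k]),
          records$reaction[k], sprintf("%.4f", records$pka[k])),
        c("id", "atom_index", "reaction", "pka")))
      sdf[[1]]
    })
    set <- methods::new("SDFset", SDF = sdfs,
                        ID = paste0(records$id, "_", records$atom_index))
    ChemmineR::write.SDF(set, path, cid = TRUE)
  }
  invisible(NULL)
}

#' Read a predictions CSV back
#' @param path CSV path written by [write_predictions()].
#' @return data.frame with the five prediction columns.
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
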