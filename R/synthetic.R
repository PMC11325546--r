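# Synthetic molecule libraries with known ground truth. Molecules are
# assembled from a fragment grammar (scaffold templates x substituents
# covering the ionizable group classes: amines, N-heterocycles, carboxylic
# acids, phenols, anilines, amides, thiols, ...), then labelled by the
# pattern oracle, with per-site pKa targets produced by a documented
# closed-form function of local structure plus Gaussian noise. Every stage
# of the pipeline is therefore trainable and testable offline, with
# recoverable generator parameters.

.SCAFFOLDS1 <- c(
  "c1ccc(%s)cc1",      # benzene
  "c1ccc(%s)cn1",      # pyridine (3-sub)
  "c1cc(%s)ccn1",      # pyridine (4-sub)
  "c1cnc(%s)cn1",      # pyrimidine
  "c1ccc(%s)s1",       # thiophene
  "c1ccc(%s)o1",       # furan
  "c1cc(%s)c[nH]1",    # pyrrole
  "c1c[nH]c(%s)n1",    # imidazole
  "c1ccc2cc(%s)ccc2c1",# naphthalene
  "C1CCC(%s)CC1",      # cyclohexane
  "C1CCC(%s)C1",       # cyclopentane
  "C1CCC(%s)NC1",      # piperidine (C-sub)
  "C1CC(%s)CN1",       # pyrrolidine (C-sub)
  "C1CCOC(%s)C1",      # oxane
  "CC%s",              # ethyl chain
  "CCC%s",             # propyl chain
  "CCCC%s",            # butyl chain
  "CC(C)%s")           # isopropyl
.SCAFFOLDS2 <- c(
  "c1cc(%s)ccc1%s",    # para-disubstituted benzene
  "c1c(%s)cccc1%s",    # ortho-disubstituted benzene
  "c1cc(%s)cc(%s)c1",  # meta-disubstituted benzene
  "c1cc(%s)cnc1%s",    # disubstituted pyridine
  "c1cc(%s)sc1%s",     # disubstituted thiophene
  "C1CC(%s)CCC1%s",    # disubstituted cyclohexane
  "C[C@@H](%s)%s",     # chiral center
  "CC(%s)C%s",         # branched chain
  "CC(%s)CC%s")        # longer branched chain
.SCAFFOLDS3 <- c(
  "c1c(%s)cc(%s)cc1%s",      # trisubstituted benzene
  "CC(%s)C(%s)C%s")          # trisubstituted chain
.SUBSTITUENTS <- c("N", "CN", "C(=O)O", "CC(=O)O", "O", "S", "CS",
                   "Cl", "F", "Br", "C", "CC", "OC", "C(=O)N",
                   "C(=O)NC", "S(=O)(=O)N", "C#N", "NC", "CCN",
                   "C(=O)OC", "NC(=O)C", "CO", "N(C)C", "CNC",
                   "C(F)(F)F", "CCl", "OCC", "CC(N)C(=O)O", "CCS")

#' Default parameters of the synthetic pKa label function
#'
#' Base pKa per oracle group class plus the structural correction terms
#' (halogens within two bonds, aromatic attachment, ring membership) and a
#' systematic `offset` used to emulate the weak-label versus experimental
#' gap.
#'
#' @return List with `base` (named numeric), `halo_2bond`,
#'   `aromatic_attach`, `in_ring`, `offset`.
#' @export
default_label_params <- function() {
  list(base = c(
    carboxylic_acid = 4.2, sulfonic_acid = 1.5, sulfinic_acid = 2.1,
    phosphonic_acid = 2.2, thioacid = 3.3, phenol = 10.0,
    thiophenol = 6.6, thiol = 10.5, imide = 9.6, sulfonamide = 10.2,
    azole_nh = 9.7, oxime = 11.3, n_hydroxy_azole = 6.0, enol = 9.2,
    imidic_oh = 7.5, guanidine = 13.6, amidine = 12.4, azine_n = 5.2,
    amine_primary = 10.6, amine_secondary = 10.9, amine_tertiary = 10.2,
    aniline = 4.6, n_alkyl_aniline = 5.1, diarylamine = 1.0,
    hydrazine = 8.1, imine = 7.0, enamine = 7.2),
    halo_2bond = -0.9,   # per halogen within two bonds of the site
    aromatic_attach = -0.5,  # site bonded to an aromatic atom
    in_ring = 0.3,       # site atom inside a ring
    offset = 0)          # systematic shift (weak vs experimental labels)
}

#' Specification of a synthetic dataset
#'
#' @param n_molecules Library size.
#' @param seed Generator seed (sampling, noise).
#' @param noise_sd Gaussian noise on pKa labels (pKa units; 0 = noiseless
#'   oracle labels).
#' @param label_params Label-function parameters; see
#'   [default_label_params()]. `offset` shifts every label systematically
#'   (used to emulate the predicted-vs-experimental gap).
#' @param backend QM backend for site energetics.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules, seed = 0L, noise_sd = 0.3,
                           label_params = default_label_params(),
                           backend = "mock") {
  structure(list(n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed), noise_sd = noise_sd,
                 label_params = label_params, backend = backend,
                 scaffolds1 = .SCAFFOLDS1, scaffolds2 = .SCAFFOLDS2,
                 scaffolds3 = .SCAFFOLDS3,
                 substituents = .SUBSTITUENTS),
            class = "synthetic_spec")
}

#' Generate a synthetic molecule library
#'
#' Seeded sampling from the fragment grammar; candidates that fail to
#' parse, standardize, or pass [element_filter()] are rejected; duplicates
#' (by canonical SMILES) are removed and the library topped up until
#' `n_molecules` unique standardized records exist.
#'
#' @param spec A `synthetic_spec`.
#' @param exclude Character vector of canonical SMILES to reject during
#'   sampling (e.g. to build a library disjoint from an existing one).
#' @return List of standardized `mol_record`s with ids `syn00001`, ...
#' @export
gen_library <- function(spec, exclude = character(0)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_molecules
  if (n == 0L) return(list())
  # the emulated corpus keeps only molecules that actually carry an
  # ionizable group, so candidates must match at least one acidic or basic
  # pattern; duplicates (by standardized canonical SMILES) are rejected and
  # sampling continues until n unique molecules exist
  patterns <- load_patterns()
  with_seed(spec$seed, {
    mols <- vector("list", n)
    kept <- 0L
    seen <- as.character(exclude)
    attempts <- 0L
    max_attempts <- 400L * n
    while (kept < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- stats::runif(1)
      smi <- if (r < 0.45) {
        sprintf(sample(spec$scaffolds1, 1), sample(spec$substituents, 1))
      } else if (r < 0.85) {
        sprintf(sample(spec$scaffolds2, 1), sample(spec$substituents, 1),
                sample(spec$substituents, 1))
      } else {
        sprintf(sample(spec$scaffolds3 %||% character(0), 1),
                sample(spec$substituents, 1), sample(spec$substituents, 1),
                sample(spec$substituents, 1))
      }
      m <- mol_from_smiles(smi, id = sprintf("syn%05d", kept + 1L))
      if (is.null(m)) next
      sm <- tryCatch(standardize(m), error = function(e) NULL)
      if (is.null(sm) || !element_filter(sm) || sm$flagged) next
      if (sm$smiles %in% seen) next
      heavy <- strip_explicit_h(sm)
      ctx <- match_context(heavy)
      ionizable <- any(vapply(patterns, function(p)
        length(match_sites(p$compiled, heavy, ctx)) > 0L, TRUE))
      if (!ionizable) next
      kept <- kept + 1L
      seen <- c(seen, sm$smiles)
      mols[[kept]] <- sm
    }
    if (kept < n)
      stop(sprintf("fragment grammar exhausted: %d unique ionizable molecules (of %d requested)",
                   kept, n))
    mols
  })
}

# Structural correction features of a site atom (1-based index on the
# heavy-atom graph): halogens within two bonds, aromatic attachment, ring
# membership. These are exactly the terms of the label function, exposed so
# recovery tests can regress against them.
site_label_features <- function(heavy, site1) {
  nb <- mol_neighbors(heavy)
  el <- heavy$atoms$element
  d1 <- nb[[site1]]
  d2 <- unique(unlist(nb[d1]))
  within2 <- setdiff(unique(c(d1, d2)), site1)
  c(n_halo = sum(el[within2] %in% c("F", "Cl", "Br", "I")),
    aromatic_attach = as.numeric(any(heavy$atoms$aromatic[d1])),
    in_ring = as.numeric(ring_atom_flags(heavy)[site1]))
}

#' Assign oracle site labels and closed-form pKa targets
#'
#' Sites come from [oracle_label()]; each site's pKa is
#' `base[class] + halo_2bond * n_halo + aromatic_attach * I(aromatic
#' neighbour) + in_ring * I(ring) + offset + N(0, noise_sd)`, clipped to
#' [0, 14]. Noise is seeded per (spec seed, molecule, site), so the same
#' spec always reproduces the same labels.
#'
#' @param mol Standardized `mol_record` from [gen_library()].
#' @param spec The `synthetic_spec`.
#' @param patterns Pattern set (default: shipped).
#' @return List: `protonation`/`deprotonation` `site_label_set`s, `pka_map`
#'   (named `"acidic:<atom>"`/`"basic:<atom>"`), and `detail` data.frame
#'   with the generator's ground-truth features per site.
#' @export
assign_labels <- function(mol, spec, patterns = load_patterns()) {
  ol <- oracle_label(mol, patterns, backend = spec$backend)
  det <- attr(ol, "sites")
  lp <- spec$label_params
  heavy <- strip_explicit_h(mol)
  pka_map <- numeric(0)
  if (nrow(det) > 0L) {
    feats <- t(vapply(seq_len(nrow(det)), function(k)
      site_label_features(heavy, det$atom_index[k] + 1L), numeric(3)))
    det <- cbind(det, as.data.frame(feats))
    det$reaction_pair <- ifelse(det$reaction == "deprotonation", "acidic",
                                "basic")
    det$pka_clean <- unname(lp$base[det$class]) +
      lp$halo_2bond * det$n_halo +
      lp$aromatic_attach * det$aromatic_attach +
      lp$in_ring * det$in_ring + lp$offset
    noise <- vapply(seq_len(nrow(det)), function(k) {
      if (spec$noise_sd == 0) return(0)
      with_seed(spec$seed + (stable_hash(paste0(mol$smiles, ":",
                                                det$reaction[k], ":",
                                                det$atom_index[k])) %% 100000L),
                stats::rnorm(1, 0, spec$noise_sd))
    }, 0)
    det$pka <- pmin(14, pmax(0, det$pka_clean + noise))
    pka_map <- stats::setNames(det$pka, paste0(det$reaction_pair, ":",
                                               det$atom_index))
  }
  list(protonation = ol$protonation, deprotonation = ol$deprotonation,
       pka_map = pka_map, detail = det)
}

#' Build a pair-example dataset from a library
#'
#' Applies the one-label-per-reaction-per-molecule convention of weak
#' macro-to-micro assignment: among labelled sites of each reaction, only
#' the lowest-energy site's pair is kept (`all_sites = TRUE` keeps all).
#'
#' @param mols List of standardized records.
#' @param spec The `synthetic_spec` (labels, backend).
#' @param schema Feature schema.
#' @param all_sites Keep every labelled site instead of the most stable
#'   one per reaction.
#' @param patterns Pattern set.
#' @return List of `pair_example`s with `target_pka` filled.
#' @export
make_pair_dataset <- function(mols, spec, schema = feature_schema(),
                              all_sites = FALSE,
                              patterns = load_patterns()) {
  out <- list()
  for (m in mols) {
    al <- assign_labels(m, spec, patterns)
    det <- al$detail
    if (is.null(det) || nrow(det) == 0L) next
    if (!all_sites) {
      keep <- unlist(lapply(split(seq_len(nrow(det)), det$reaction),
                            function(ix) ix[which.min(det$energy[ix])]))
      det <- det[sort(keep), , drop = FALSE]
    }
    labs <- list(
      protonation = structure(list(mol_id = m$id,
        labels = as.integer(seq_len(n_atoms(m)) %in%
                              (det$atom_index[det$reaction == "protonation"] + 1L)),
        reaction = "protonation"), class = "site_label_set"),
      deprotonation = structure(list(mol_id = m$id,
        labels = as.integer(seq_len(n_atoms(m)) %in%
                              (det$atom_index[det$reaction == "deprotonation"] + 1L)),
        reaction = "deprotonation"), class = "site_label_set"))
    prs <- build_pairs(m, labs, backend = spec$backend, schema = schema,
                       pka_map = al$pka_map)
    out <- c(out, prs)
  }
  out
}

#' Build a node-classification dataset from a library
#'
#' One example per molecule: the featurized graph plus the oracle's binary
#' site labels for the requested reaction.
#'
#' @param mols List of standardized records.
#' @param spec The `synthetic_spec`.
#' @param reaction `"protonation"` or `"deprotonation"`.
#' @param schema Feature schema.
#' @param patterns Pattern set.
#' @return List of `list(graph, labels, id)` usable by
#'   [train_site_model()].
#' @export
make_site_dataset <- function(mols, spec,
                              reaction = c("protonation", "deprotonation"),
                              schema = feature_schema(),
                              patterns = load_patterns()) {
  reaction <- match.arg(reaction)
  make_site_datasets(mols, spec, schema, patterns)[[reaction]]
}

#' Build node-classification datasets for both reactions at once
#'
#' Shares the oracle labelling and featurization between the protonation
#' and deprotonation datasets (each molecule is labelled and featurized
#' once).
#'
#' @inheritParams make_site_dataset
#' @return List with elements `protonation` and `deprotonation`, each a
#'   dataset for [train_site_model()].
#' @export
make_site_datasets <- function(mols, spec, schema = feature_schema(),
                               patterns = load_patterns()) {
  prot <- vector("list", length(mols))
  deprot <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    ol <- oracle_label(m, patterns, backend = spec$backend)
    g <- featurize(m, compute_qm(m, spec$backend), schema)
    prot[[k]] <- list(graph = g, labels = ol$protonation$labels, id = m$id)
    deprot[[k]] <- list(graph = g, labels = ol$deprotonation$labels,
                        id = m$id)
  }
  list(protonation = prot, deprotonation = deprot)
}

#' Build the two-stage synthetic benchmark
#'
#' A large weak-label pretraining set and a small disjoint
#' "experimental" fine-tuning set whose label function is shifted by a
#' documented systematic offset (and may use a different noise level),
#' emulating the predicted-versus-measured gap.
#'
#' @param spec_weak,spec_exp `synthetic_spec`s for the two stages
#'   (molecules overlapping the weak set are removed from the experimental
#'   set and logged).
#' @return List `weak` (pair examples), `exp` (pair examples), `manifest`
#'   (specs minus closures, seeds, counts).
#' @export
make_benchmark <- function(spec_weak, spec_exp) {
  mw <- gen_library(spec_weak)
  weak_smiles <- vapply(mw, `[[`, "", "smiles")
  # the experimental library is drawn disjoint from the weak one
  me <- gen_library(spec_exp, exclude = weak_smiles)
  dup <- vapply(me, function(m) m$smiles %in% weak_smiles, TRUE)
  if (any(dup)) {
    mp_log("info", "benchmark",
           sprintf("%d overlapping molecules removed from experimental set",
                   sum(dup)))
    me <- me[!dup]
  }
  weak <- make_pair_dataset(mw, spec_weak)
  exper <- make_pair_dataset(me, spec_exp)
  manifest <- list(
    weak = list(n_molecules = spec_weak$n_molecules, seed = spec_weak$seed,
                noise_sd = spec_weak$noise_sd,
                offset = spec_weak$label_params$offset,
                n_pairs = length(weak)),
    exp = list(n_molecules = spec_exp$n_molecules, seed = spec_exp$seed,
               noise_sd = spec_exp$noise_sd,
               offset = spec_exp$label_params$offset,
               n_pairs = length(exper), n_overlap_removed = sum(dup)))
  list(weak = weak, exp = exper, manifest = manifest)
}
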