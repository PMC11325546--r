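# Shared fixtures, built lazily once per test run and cached in this
# environment. Everything is generated in code (no binary fixtures).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Quiet OpenBabel's stderr chatter in tests where we parse junk on purpose.
quiet_ob <- function(expr) suppressWarnings(suppressMessages(expr))

std_mol <- function(smiles, id = "m") standardize(mol_from_smiles(smiles, id))

# A small standardized molecule set reused across files.
fix_mols <- function() fixture("mols", function() {
  list(
    benzene = std_mol("c1ccccc1", "benzene"),
    pyridine = std_mol("c1ccncc1", "pyridine"),
    phenol = std_mol("Oc1ccccc1", "phenol"),
    acetic = std_mol("CC(=O)O", "acetic"),
    ethanol = std_mol("CCO", "ethanol"),
    alanine = std_mol("N[C@@H](C)C(=O)O", "alanine"),
    paba = std_mol("OC(=O)c1ccc(N)cc1", "paba"))
})

# Small synthetic library + site dataset + trained tiny models used by the
# pipeline/cli tests (model quality is irrelevant there; determinism and
# contracts are what is tested).
fix_tiny_models <- function() fixture("tiny_models", function() {
  spec <- synthetic_spec(60, seed = 5, noise_sd = 0)
  mols <- gen_library(spec)
  scfg <- site_model_config(max_epochs = 25L, patience = 6L, seed = 0L)
  mp <- train_site_model(make_site_dataset(mols, spec, "protonation"),
                         scfg, "protonation")
  md <- train_site_model(make_site_dataset(mols, spec, "deprotonation"),
                         scfg, "deprotonation")
  pairs <- make_pair_dataset(mols, spec)
  pcfg <- pka_model_config(n_layers = 2L, hidden = 24L,
                           head_hidden = c(24L), batch_size = 64L,
                           max_epochs = 40L, patience = 10L, seed = 0L)
  pk <- pretrain(pka_model_init(pcfg), pairs,
                 train_plan(pretrain_epochs = 40L, patience = 10L,
                            seed = 0L))
  list(spec = spec, mols = mols, sites_prot = mp, sites_deprot = md,
       pka = pk, pairs = pairs)
})
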