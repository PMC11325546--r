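---
title: "Site-specific micro-pKa prediction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific micro-pKa prediction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The acidity of a drug-like molecule is site-specific: a molecule with
several ionizable groups has one micro-pKa per protonation or
deprotonation site, and downstream properties (charge state at
physiological pH, permeability, binding) depend on the *site-resolved*
values, not a single macroscopic constant. `micropka` implements a
three-stage workflow for predicting these values from structure alone:

1. **Tautomer selection.** The neutral input structure is enumerated into
   its proton-shift tautomers and the most stable form — by total
   semiempirical energy in implicit water — is carried forward. Which
   tautomer dominates in solution changes which sites exist and how acidic
   they are, so this step precedes everything else.
2. **Reaction-site enumeration.** Two graph neural network (GNN) node
   classifiers (one for protonation, one for deprotonation) mark the atoms
   likely to gain or lose a proton. They are trained on labels produced by
   the package's ionizable-group pattern oracle combined with two physical
   filters (below).
3. **Micro-pKa regression.** For each predicted site the package builds the
   (protonated form, deprotonated form) pair of molecular graphs; both pass
   through a shared GNN encoder with global mean pooling, the pooled
   vectors are concatenated with each form's molecular descriptor vector,
   and linear layers regress a single pKa for that site.

The glue conventions: *acidic* pKa means removal of a proton from the
neutral form (the neutral molecule is the protonated branch of the pair);
*basic* pKa means protonation of the neutral base (the neutral molecule is
the deprotonated branch). Atom indices are 0-based in every file and
user-facing structure.

## Molecular representation

Molecules are plain molecular graphs (atom table, bond table with orders
1/1.5/2/3, tetrahedral stereo tags, one conformer). SMILES
canonicalization and validation are delegated to OpenBabel through
ChemmineOB; every structure the package edits (protomers, deprotomers,
tautomers) must survive an OpenBabel canonicalization round trip or it is
discarded. Standardization keeps the largest covalent fragment,
neutralizes simple ±1 protonation states (−1 on O/N/S gains a proton, +1
on an H-bearing N loses one), converts to canonical atom order, makes all
hydrogens explicit graph nodes, and embeds one conformer.

Hydrogens are explicit nodes deliberately: deprotonation sites are
H-bearing atoms, and the node-classification output must have one entry
per atom including hydrogens.

**Conformers.** Coordinates come from classical multidimensional scaling
of the graph distance matrix (1.5 Å per bond) plus a small deterministic
jitter seeded from the *stereo-stripped* canonical SMILES. This gives
reproducible, chemically plausible extents for the shape descriptors
without an external force field, and guarantees bit-identical coordinates
for enantiomers — which, combined with reflection-invariant descriptors,
makes the entire pipeline exactly invariant under mirror inversion
(`invert_stereocenters()` additionally mirrors the parent conformer
explicitly, per the augmentation convention). The cost is that these are
not physical 3D geometries: descriptor *values* are internally consistent
rather than comparable to crystallographic ones.

## Semiempirical features and the mock backend

The models consume per-atom partial charges, Fukui indices (f+, f0, f−),
coordination numbers, polarizabilities, per-bond Wiberg bond orders, and
total energies. The backend contract has two implementations:

* `gfn2xtb` shells out to an external GFN2-xTB executable (single point,
  ALPB water) when one is on the PATH, raising a structured
  `backend_unavailable` / `backend_failure` condition otherwise so one
  molecule's failure never aborts a batch.
* `mock` (default) computes deterministic graph-derived surrogates, making
  the whole workflow trainable and testable offline:
  * charges: one electronegativity-equalization sweep over the bond graph,
    `q_i = Σ_j 0.6·order_ij·(EN_j − EN_i)/(EN_i + EN_j)` plus 0.7·(formal
    charge), with the residual placed on the highest-degree atom so the
    sum equals the net charge exactly (to rounding, < 1e−12 e);
  * coordination number: heavy-atom degree + 0.5 × bonded hydrogens;
  * polarizability: free-atom values (a.u.) with a small aromatic bonus;
  * Wiberg order: the integer/aromatic bond order attenuated by
    electronegativity mismatch, always > 0;
  * total energy (Hartree): element terms + bond-order terms + aromatic
    and carbonyl stabilization − quadratic net-charge penalty, plus a
    ≤ 5e−4 Ha jitter hashed from the stereo-stripped canonical SMILES so
    constitutional isomers rank deterministically but enantiomers and
    atom permutations score identically. The carbonyl term makes
    keto/amide/lactam forms more stable than their enol/imidic/lactim
    partners, matching the dominant tautomer for the vast majority of
    real molecules.

Energies are converted with 27.211386 eV/Hartree. Fukui indices use the
same solvation setting as the energy; the mock backend flags results as
solvated by default.

## Tautomer enumeration

The transform set is deliberately explicit, because tautomer enumerations
differ between toolkits: keto↔enol, amide↔imidic acid, and aromatic
lactam↔lactim (2-pyridone-type), applied breadth-first with
canonical-SMILES deduplication, formula/charge conservation checks, and a
cap (`max_tautomers`, default 64, warning on truncation). Acid, base and
zwitterion tautomer searches are excluded — the search operates on neutral
forms only, and charged inputs are an error directing the caller to
standardize first. Ties in energy break to the lexicographically smallest
canonical SMILES, which makes selection permutation-invariant.

## Site labelling: pattern oracle + physical filters

Training labels come from a shipped plain-text pattern file
(`inst/extdata/ionizable_patterns.smarts`, 29 patterns) written in a
documented SMARTS subset (element/aromaticity, H/D/X counts, ring and
ring-size primitives, charges, `!`/`,`/`;` logic; no recursive SMARTS —
the matcher refuses patterns it cannot honour). The first atom of each
pattern is the site atom. One code-level exclusion supplements the
patterns: a nitrogen bonded to a carbonyl- or sulfonyl-type neighbour
(amide/sulfonamide N) is never labelled basic.

Every putative site is then verified physically:

* the **structural-change filter** demands that the edited structure,
  after deleting the transferred proton, is graph-isomorphic to the parent
  with identical heavy-atom bond orders — edits that open rings or
  rearrange are rejected;
* the **energy window** keeps only products within 10 eV (inclusive) of
  the lowest-energy product of the same reaction.

Ionizable groups outside the 0–14 pKa range (aliphatic alcohols, amide
N–H, carbon acids, ether/thioether protonation) are deliberately absent
from the pattern file, mirroring the training-range filter; carbon-acid
sites are therefore invisible to the trained models.

## Graph features

The node-feature schema is locked at **exactly 61 features** (a unit test
guards the total): one-hots for atom type (11), formal charge (5), degree
(6), total hydrogen count (5), hybridization (4), valence (7), smallest
ring size (6); flags for aromaticity, ring membership, H-bond donor/
acceptor, heteroatom, terminal atom; scalars for electronegativity,
covalent radius, mass, lone pairs, heavy degree; and the six
semiempirical slots (partial charge, f+, f0, f−, coordination number,
polarizability). Edges carry a bond-type one-hot (single first),
conjugation, ring membership and the Wiberg order, identically on both
directed arcs. Molecular features are RadiusOfGyration, Eccentricity,
Spherocity, FractionCSP3, Asphericity and the protonation energy
E(protonated) − E(deprotonated) ("xTB-Energy", Hartree; populated only
for pairs, shared by both graphs of a pair).

Shape descriptors come from the mass-weighted gyration tensor with
eigenvalues l1 ≥ l2 ≥ l3: Rg = √(l1+l2+l3), Asphericity =
((l1−l2)² + (l2−l3)² + (l1−l3)²) / (2(l1+l2+l3)²) (0 for a sphere, 1 for
a line), Eccentricity = √(1 − l3²/l1²), Spherocity = 3·l3/(l1+l2+l3).
Degenerate inputs (fewer than three atoms, coincident coordinates) return
0 for all four rather than NaN. None of the node, edge or molecular
features depends on stereo tags or handedness — this is what makes
enantiomer invariance exact rather than approximate.

The schema is hashed; models store the hash and refuse graphs built under
a different schema.

## The networks

Three message-passing families are implemented behind one interface:
`gcn` (degree-normalized convolution with self-loops), `gat` (additive
attention with edge-feature scores) and `gtr` (dot-product attention).
All include a learned projection of edge features into the messages, ReLU
activations, and — for the regression task — global mean pooling and a
linear head. Everything is dense base-R matrix algebra with hand-derived
reverse-mode gradients (verified against central finite differences in
the test suite, including the input-feature gradients that integrated
gradients relies on) and an Adam optimizer. Molecule batches are merged
block-diagonally, so one training step is a handful of BLAS calls.

Defaults (chosen once for the package's study conditions): site models —
GCN, 3 layers × 48 hidden units, positive-class-weighted binary
cross-entropy (the weight is the training-set negative:positive ratio;
most atoms are not sites), threshold 0.5, ≤ 60 epochs with patience 10;
pKa model — GCN, 3 layers × 48, head 48→24→1, mean squared error on
targets standardized by the pretraining-set mean and standard deviation
(the model stores the normalization and undoes it at prediction time;
this is what lets 100-epoch budgets converge), batch 256, learning rate
5e−3 pretraining / 1.5e−3 fine-tuning, patience 15. The two encoder
branches of the pair model share weights, halving parameters and
enforcing representational symmetry between the protonated and
deprotonated forms. Splits are always by molecule, never by atom or site:
80:10:10 for pretraining, 80:20 for fine-tuning. Training is
deterministic given the seed: initialization, minibatch partition and
epoch-order shuffling all derive from it.

## Synthetic data: what it emulates, what it does not

The generator assembles molecules from a fragment grammar (aromatic and
saturated scaffolds × substituents spanning amines, anilines,
N-heterocycles, carboxylic acids, phenols, thiols, amides, sulfonamides,
halogens and inert decorations), standardizes them, and keeps only unique
molecules that carry at least one ionizable-group match — mirroring a
training corpus filtered to molecules with acidic or basic pKa between 0
and 14. Site labels come from the same oracle the site models train on;
pKa targets are a documented closed-form function of local structure:

    pKa = base(group class) − 0.9·(halogens within 2 bonds)
          − 0.5·(aromatic attachment) + 0.3·(ring membership)
          + offset + N(0, noise_sd),  clipped to [0, 14]

with per-class base values (carboxylic acid 4.2, phenol 10.0, pyridine-type
N 5.2, primary amine 10.6, guanidine 13.6, …) kept in the spec so recovery
tests can regress against the exact generating features. Defaults:
`noise_sd = 0.3` (a realistic label-noise scale for predicted pKa data);
0 for oracle-equivalence tests. The weak-label/experimental benchmark
uses a documented systematic offset (+0.6) and noise 0.2 for the
"experimental" set, emulating the predicted-versus-measured gap, with
molecule-level disjointness enforced.

Pair datasets follow the one-label-per-reaction convention: among a
molecule's labelled sites of one reaction, only the lowest-energy site's
pair is kept (mimicking macro-to-micro label assignment in weakly
labelled corpora); `all_sites = TRUE` disables this.

What passing tests on this material *does* show: the architecture can
learn a local-structure-determined pKa function through the paired-graph
bottleneck; transfer learning moves the model across a systematic label
shift more efficiently than training from scratch; the pipeline's
invariances (enantiomers, atom order, worker count) hold exactly. What it
does *not* show: accuracy on real experimental pKa data, which depends on
real semiempirical features, conformers and label quality that the mock
backend and grammar do not emulate.

## Study conditions and problem sizes

The acceptance battery (mirrored by `scripts/acceptance.R`) uses: a
500-molecule oracle-labelled library for the site classifiers (held-out
per-atom accuracy ≥ 0.95 for both reactions); 2000 noiseless pairs from a
1600-molecule library for pretraining (held-out RMSE ≤ 0.5 pKa units); a
disjoint experimental-style set of 200 training pairs plus a held-out
remainder for the five-seed transfer-versus-scratch comparison;
integrated-gradients completeness at 128 steps within 1%; and 50 chiral
molecules for the end-to-end enantiomer check at 1e−6. These sizes were
fixed as the package's study conditions together with the training
defaults above.

## Numerical and edge-case decisions

* pKa range bounds inclusive; energy-window boundary inclusive.
* Tautomer/selection ties break lexicographically on canonical SMILES.
* Symmetry-equivalent sites legitimately tie at relative energy 0; the
  "unique minimum" property holds only up to molecular symmetry.
* Meso-like cases: the inverted form is emitted only when its canonical
  SMILES differs from the parent's; otherwise no augmentation.
* E/Z double-bond markers are parsed and dropped; only tetrahedral stereo
  is tracked (the augmentation operations only involve tetrahedral
  centres).
* Zero-variance truth vectors make R² undefined; `evaluate()` returns a
  flagged `NA` rather than NaN.
* Fingerprints for Tanimoto overlap filtering are OpenBabel FP2 path
  fingerprints (1024 bits); the 0.8 overlap threshold is applied to the
  maximum coefficient against the training set.
* Integrated gradients use the midpoint Riemann rule; for an affine
  model one step is already exact, and completeness is tested both ways.
* Model artifacts are JSON (weights with explicit dimensions, config,
  schema hash, stage provenance, seeds) so they survive in text-only
  repositories and can be diffed.

## Known limitations

* The mock backend is a graph-level surrogate: its charges and Fukui
  indices are chemically plausible but not quantum-mechanical; models
  trained on it do not transfer to real data without retraining against a
  real backend.
* Tautomer enumeration covers the three dominant proton-shift families
  only; exotic tautomerism (ring-chain, valence) is out of scope.
* The SMARTS subset excludes recursive environments; patterns requiring
  them must be expressed through code-level exclusion rules.
* Conformers are MDS embeddings, not minimized geometries.
* Carbon acids and groups outside 0–14 are invisible to the models by
  construction of the training patterns.
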