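Package: micropka
Title: Site-Specific Micro-pKa Prediction with Paired Graph Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for predicting site-specific (micro) acid dissociation
    constants of drug-like organic molecules. The pipeline selects the most
    stable neutral tautomer by semiempirical total energy, enumerates
    protonation and deprotonation sites with trainable graph neural network
    node classifiers, and predicts the micro-pKa of each site with a
    paired-graph regression model (protonated and deprotonated forms encoded
    jointly) trained by pretraining on large weakly labelled data and
    fine-tuning on small experimental-style data. Includes a deterministic
    mock semiempirical backend, an optional adapter to an external GFN2-xTB
    executable, a documented ionizable-group pattern oracle, and a seeded
    synthetic molecule and label generator so every stage is trainable and
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    yaml,
    methods,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
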