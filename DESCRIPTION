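Package: inertforge
Title: Curation and Generative Expansion of Biologically Inactive Compound Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for building negative-data libraries for ligand-based
    virtual screening. Curates consistently inactive compounds from bioassay
    result tables using an entropy-based assay-diversity score, expands the
    curated set with a character-level LSTM SMILES generator (augmentation,
    temperature sampling, generation-frequency filtering), evaluates the
    generator with validity/uniqueness/novelty and scaffold/fragment cosine
    similarity, profiles compound sets (Lipinski rules, PAINS substructure
    flags, ECFP4 fingerprints, Tanimoto similarity, Murcko scaffolds, BRICS
    fragments, scaffold enrichment), and benchmarks how the choice of
    negative-label compounds affects fingerprint random-forest activity
    classifiers over repeated hold-out splits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    ranger,
    stats,
    utils,
    uwot
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel command-line tools (obabel)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
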